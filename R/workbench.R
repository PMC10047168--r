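#' Read a model configuration file
#'
#' Plain-text `key = value` format with one `[section]` per model. Each
#' section must name a built-in model family via `model = toy` or
#' `model = pdpc`; every other key is passed as a numeric parameter. Lines
#' starting with `#` are comments.
#'
#' @param path Path to the configuration file.
#' @return Named list of [state_graph_model()]s, one per section.
#' @export
read_model_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  models <- list()
  section <- NULL
  keys <- list()
  flush <- function() {
    if (is.null(section)) return()
    if (is.null(keys$model)) {
      stop("config section [", section, "] does not name a model", call. = FALSE)
    }
    fam <- keys$model
    keys$model <- NULL
    models[[section]] <<- builtin_model(fam, lapply(keys, as.numeric))
  }
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      flush()
      section <- gsub("^\\[|\\]$", "", ln)
      keys <- list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (is.null(section)) stop("key outside any [section]: ", ln, call. = FALSE)
      keys[[trimws(kv[1])]] <- trimws(paste(kv[-1], collapse = "="))
    } else {
      stop("cannot parse config line: ", ln, call. = FALSE)
    }
  }
  flush()
  models
}

#' Write a lattice distribution as a tab-separated table
#'
#' Columns `n_1 ... n_M` and `probability`, preceded by `#`-prefixed
#' provenance header lines (model, parameters, N, and any extra metadata
#' such as `log C(N)` or mode locations).
#'
#' @param dist A [lattice_distribution()].
#' @param path Output file path.
#' @param metadata Named list of scalar metadata written into the header.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path, metadata = list()) {
  stopifnot(inherits(dist, "lattice_distribution"))
  lat <- dist$lattice
  hdr <- c(sprintf("# N = %d", lat$N), sprintf("# M = %d", lat$M))
  for (k in names(metadata)) {
    hdr <- c(hdr, sprintf("# %s = %s", k, format(metadata[[k]], digits = 15)))
  }
  tab <- data.frame(lat$states, probability = dist$prob)
  names(tab) <- c(paste0("n_", seq_len(lat$M)), "probability")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a distribution written by [write_distribution()]
#'
#' @param path Input file path.
#' @return A [lattice_distribution()]; header metadata is attached as the
#'   `"metadata"` attribute.
#' @export
read_distribution <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- list()
  for (h in hdr) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  tab <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           header = TRUE, sep = "\t")
  M <- sum(startsWith(names(tab), "n_"))
  N <- sum(as.numeric(tab[1, seq_len(M)]))
  lat <- simplex_lattice(N, M)
  prob <- numeric(lat$size)
  prob[lattice_index(lat, as.matrix(tab[, seq_len(M)]))] <- tab$probability
  dist <- lattice_distribution(lat, prob)
  attr(dist, "metadata") <- meta
  dist
}

#' Export a three-species distribution as a dense heatmap grid
#'
#' Writes the rescaled probabilities `rho(n_A, n_C) / rho_max` as an
#' `(N + 1) x (N + 1)` tab-separated grid (rows `n_A`, columns `n_C`), with
#' zeros outside the simplex and `rho_max` recorded in the `#` header. This
#' is the representation in which bistable stationary distributions are
#' usually plotted.
#'
#' @param dist A [lattice_distribution()] with `M = 3`.
#' @param path Output file path.
#' @return `path`, invisibly; the maximum probability is attached as the
#'   `"rho_max"` attribute.
#' @export
export_heatmap <- function(dist, path) {
  stopifnot(inherits(dist, "lattice_distribution"))
  lat <- dist$lattice
  if (lat$M != 3) {
    stop("unsupported-shape error: heatmap export requires M = 3", call. = FALSE)
  }
  N <- lat$N
  rho_max <- max(dist$prob)
  grid <- matrix(0, N + 1, N + 1, dimnames = list(0:N, 0:N))
  grid[cbind(lat$states[, 1] + 1L, lat$states[, 3] + 1L)] <- dist$prob / rho_max
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# rho_max = %s", format(rho_max, digits = 15)),
               sprintf("# N = %d", N),
               "# rows: n_A = 0..N, columns: n_C = 0..N"), con)
  utils::write.table(grid, con, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(structure(path, rho_max = rho_max))
}

#' Specification of a parameter/size sweep
#'
#' Bundles everything needed to reproduce an error-vs-N experiment: the
#' model family, the swept parameter grid, the particle-number grid, the
#' methods to evaluate and the reference to compare against.
#'
#' @param model Model family name (`"toy"` or `"pdpc"`).
#' @param fixed Named list of parameters held fixed.
#' @param sweep_param Name of the swept parameter.
#' @param param_grid Numeric grid of swept values.
#' @param N_grid Integer grid of particle numbers.
#' @param methods Methods to evaluate (subset of
#'   `c("rwa", "sse", "multinomial", "exact", "gillespie")`).
#' @param reference Reference method.
#' @param seed Integer seed for stochastic cells.
#' @return Object of class `"sweep_spec"`.
#' @export
sweep_spec <- function(model, fixed = list(), sweep_param, param_grid,
                       N_grid, methods = c("rwa", "sse", "multinomial"),
                       reference = "exact", seed = 1L) {
  if (!length(param_grid) || !length(N_grid)) {
    stop("validation error: parameter and N grids must be non-empty",
         call. = FALSE)
  }
  if (!length(methods) ||
      !all(methods %in% c("rwa", "sse", "multinomial", "exact", "gillespie"))) {
    stop("validation error: methods must be a non-empty subset of rwa/sse/multinomial/exact/gillespie",
         call. = FALSE)
  }
  structure(list(model = model, fixed = fixed, sweep_param = sweep_param,
                 param_grid = param_grid, N_grid = N_grid, methods = methods,
                 reference = reference, seed = as.integer(seed)),
            class = "sweep_spec")
}

#' Run a sweep and collect a long-format results table
#'
#' One row per (parameter value, N, method, metric). Deterministic given the
#' spec's seed. When `out` points to an existing results file, cells already
#' present are skipped and the table is extended (resumability); per-cell
#' solver failures are logged as `NA` rows and the sweep continues.
#'
#' @param spec A [sweep_spec()].
#' @param out Optional path of a TSV results file for resumable execution.
#' @param verbose Print per-cell progress.
#' @return Long-format `data.frame` with columns `param`, `N`, `method`,
#'   `metric`, `value`.
#' @export
run_sweep <- function(spec, out = NULL, verbose = FALSE) {
  stopifnot(inherits(spec, "sweep_spec"))
  done <- if (!is.null(out) && file.exists(out)) {
    utils::read.table(out, header = TRUE, sep = "\t")
  } else NULL

  rows <- list()
  for (par in spec$param_grid) {
    for (N in spec$N_grid) {
      params <- spec$fixed
      params[[spec$sweep_param]] <- par
      model <- builtin_model(spec$model, params)
      cell_done <- !is.null(done) &&
        any(done$param == par & done$N == N & done$method %in% spec$methods)
      if (cell_done) next
      cell <- tryCatch({
        cmp <- compare_methods(model, N, methods = spec$methods,
                               reference = spec$reference, seed = spec$seed)
        do.call(rbind, lapply(seq_len(nrow(cmp)), function(i) {
          data.frame(param = par, N = N, method = cmp$method[i],
                     metric = c("l1", "js", "cov_error"),
                     value = c(cmp$l1[i], cmp$js[i], cmp$cov_error[i]))
        }))
      }, error = function(e) {
        warning("sweep cell (", spec$sweep_param, " = ", par, ", N = ", N,
                ") failed: ", conditionMessage(e))
        data.frame(param = par, N = N, method = spec$methods[1],
                   metric = "failed", value = NA_real_)
      })
      if (verbose) {
        message(sprintf("sweep: %s = %g, N = %d done", spec$sweep_param, par, N))
      }
      rows[[length(rows) + 1]] <- cell
    }
  }
  res <- do.call(rbind, c(list(done), rows))
  if (!is.null(out)) {
    utils::write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
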