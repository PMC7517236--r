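#' Write / read a CSV table with a metadata header
#'
#' Writes `#`-prefixed metadata lines (package version, timestamp-free
#' config echo) followed by a comma-separated table with a header row.
#' Numeric columns are rendered with 17 significant digits so a re-read
#' reproduces the doubles bit-exactly.
#'
#' @param df a data.frame.
#' @param path output file path.
#' @param meta character vector of metadata lines (without the leading
#'   `#`).
#' @return `path`, invisibly.
#' @export
write_ctrw_csv <- function(df, path, meta = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ctrwtails %s",
                     as.character(utils::packageVersion("ctrwtails"))), con)
  for (mline in meta) writeLines(paste0("# ", mline), con)
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]]))
      out[[j]] <- formatC(out[[j]], digits = 17, format = "g")
  utils::write.table(out, con, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ctrw_csv
#' @export
read_ctrw_csv <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Compare two methods evaluated on a shared grid
#'
#' @param grid numeric grid both methods were evaluated on.
#' @param a,b numeric vectors of the two methods' values on `grid`.
#' @param labels length-2 character, names of the methods.
#' @return object of class `ctrw_compare`: list with the per-point
#'   `table` (grid, both values, absolute and relative difference) and
#'   the summary scalars `max_abs_diff`, `max_rel_diff`.
#' @export
compare_methods <- function(grid, a, b, labels = c("a", "b")) {
  if (length(a) != length(grid) || length(b) != length(grid))
    stop("mismatched grids: all inputs must share one grid")
  rel <- abs(a - b) / pmax(abs(a), abs(b), .Machine$double.xmin)
  tab <- data.frame(grid = grid, a = a, b = b,
                    abs_diff = abs(a - b), rel_diff = rel)
  names(tab)[2:3] <- labels
  structure(list(table = tab, labels = labels,
                 max_abs_diff = max(abs(a - b)), max_rel_diff = max(rel)),
            class = "ctrw_compare")
}

#' @export
print.ctrw_compare <- function(x, ...) {
  cat(sprintf("Method comparison %s vs %s over %d points\n",
              x$labels[1], x$labels[2], nrow(x$table)))
  cat(sprintf("  max |diff| = %.6g, max rel diff = %.6g\n",
              x$max_abs_diff, x$max_rel_diff))
  invisible(x)
}

#' Regenerate the data behind the package's reference comparisons
#'
#' Each name returns the table of one standard comparison as a
#' data.frame (no plotting; the tables are the product):
#'
#' * `"fig1"`: exponential waiting + gaussian jumps at t = 2 — exact
#'   series density, saddle-point density, and the central Gaussian
#'   approximation on an |x| <= 30 grid. The saddle form tracks the
#'   exact curve into the far tail; the Gaussian fails there.
#' * `"fig5"`: erlang counts at rescaled time t/m = 1 for m = 1, 2, 3 —
#'   exact \eqn{Q_t(n)} against the Stirling-route approximation
#'   \eqn{H (2\pi m n)^{-1/2} e^{-mn I_n(l)}} with the small-l geometric
#'   H.
#' * `"fig9"`: erlang counts at t = 400 for m = 1, 2, 4 — exact against
#'   the central-limit Gaussian; larger m narrows the distribution
#'   (anti-bunching kills count fluctuations).
#' * `"fig11"`: two-exponential counts at t = 2 for a = 0.5 and 0.9
#'   (with a + b = 2) — exact against the universal large-n law;
#'   convergence is slow for strong bunching (small a).
#'
#' @param name one of `"fig1"`, `"fig5"`, `"fig9"`, `"fig11"`.
#' @return a data.frame; see above for columns.
#' @export
figure_data <- function(name = c("fig1", "fig5", "fig9", "fig11")) {
  name <- match.arg(name)
  switch(name,
    fig1 = {
      w <- make_waiting_time("exponential"); j <- make_jump("gaussian")
      x <- seq(-30, 30, by = 0.25)
      ps <- propagator_series(w, j, t = 2, x = x)
      sd_log <- saddle_log_density(w, j, x, t = 2)
      gauss <- stats::dnorm(x, 0, sqrt(2))
      data.frame(x = x, exact = ps$density, saddle = exp(sd_log),
                 gaussian = gauss)
    },
    fig5 = {
      do.call(rbind, lapply(c(1L, 2L, 3L), function(m) {
        w <- make_waiting_time("erlang", m = m)
        t <- m  # rescaled time t/m = 1
        n <- 1:30
        exact <- exp(qtn_exact_log(w, t, n))
        l <- t / (n * m)
        stirling <- erlang_H(t, l, m, form = "limit") /
          sqrt(2 * pi * m * n) * exp(-m * n * rate_In(l))
        data.frame(m = m, n = n, exact = exact, stirling = stirling)
      }))
    },
    fig9 = {
      do.call(rbind, lapply(c(1L, 2L, 4L), function(m) {
        w <- make_waiting_time("erlang", m = m)
        t <- 400
        mu <- t / m; sd <- sqrt(t) / m
        n <- max(0, floor(mu - 6 * sd)):ceiling(mu + 6 * sd)
        data.frame(m = m, n = n, exact = exp(qtn_exact_log(w, t, n)),
                   clt = qtn_clt(w, t, n))
      }))
    },
    fig11 = {
      do.call(rbind, lapply(c(0.5, 0.9), function(a) {
        w <- make_waiting_time("two_exponential", a = a, b = 2 - a)
        n <- 0:40
        exact <- qtn_exact(w, t = 2, n_max = 40)$prob
        large_n <- c(NA, qtn_large_n(w, t = 2, n = 1:40))
        data.frame(a = a, n = n, exact = exact, large_n = large_n)
      }))
    })
}
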