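#' Highest-posterior-density interval
#'
#' Empirical shortest-interval estimator: the narrowest contiguous window
#' of the sorted draws containing `ceiling(level * n)` points.
#'
#' @param draws numeric sample vector.
#' @param level interval mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, level = 0.95) {
  n <- length(draws)
  stopifnot(n >= 1, level > 0, level <= 1)
  s <- sort(draws)
  m <- ceiling(level * n)
  if (m >= n) return(c(s[1], s[n]))
  starts <- seq_len(n - m + 1)
  widths <- s[starts + m - 1] - s[starts]
  i <- which.min(widths)
  c(s[i], s[i + m - 1])
}

#' Effective sample size
#'
#' `n / (1 + 2 * sum(rho_k))` with autocorrelations accumulated under
#' Geyer's initial-positive-sequence rule: lag pairs
#' `(rho_1 + rho_2), (rho_3 + rho_4), ...` are summed until the first
#' non-positive pair.  Capped at `n` (antithetic chains) and floored at 1.
#'
#' @param draws numeric chain (order matters).
#' @return effective sample size in `(0, n]`.
#' @export
effective_sample_size <- function(draws) {
  n <- length(draws)
  if (n < 10) stop("need at least 10 draws")
  if (stats::var(draws) == 0) {
    warning("zero-variance chain; reporting ESS = n")
    return(n)
  }
  lag_max <- min(n - 2L, 2000L)
  rho <- stats::acf(draws, lag.max = lag_max, plot = FALSE,
                    demean = TRUE)$acf[-1]
  tau <- 1
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    k <- k + 2L
  }
  tau <- max(tau, 1)     # negative-autocorrelation chains cap at ESS = n
  min(n / tau, n)
}

#' Summarize a parameter's posterior draws
#'
#' Posterior mean, posterior standard deviation (PSD), 95% HPD bounds,
#' effective sample size, and an HPD-based significance flag (interval
#' excludes zero).
#'
#' @param draws numeric sample vector (>= 10 draws).
#' @param level HPD mass (default 0.95).
#' @param name parameter label.
#' @return one-row data.frame with columns name, mean, psd, hpd_low,
#'   hpd_high, ess, significant.
#' @export
summarize_draws <- function(draws, level = 0.95, name = "parameter") {
  if (length(draws) < 10) stop("need at least 10 draws")
  hpd <- hpd_interval(draws, level)
  ess <- suppressWarnings(effective_sample_size(draws))
  data.frame(name = name,
             mean = mean(draws),
             psd = stats::sd(draws),
             hpd_low = hpd[1], hpd_high = hpd[2],
             ess = ess,
             significant = !(hpd[1] <= 0 && hpd[2] >= 0),
             stringsAsFactors = FALSE)
}

#' Export trace plots and a tidy draws file
#'
#' Writes one image per parameter and a single TSV of the draws.  Plotting
#' failures are caught so they never corrupt the numeric output.
#'
#' @param draws matrix (one column per parameter) or numeric vector.
#' @param labels parameter names; defaults to column names.
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"pdf"`.
#' @return invisible character vector of the files written.
#' @export
export_traces <- function(draws, labels = NULL, dir, format = c("png", "pdf")) {
  format <- match.arg(format)
  if (is.vector(draws)) draws <- matrix(draws, ncol = 1)
  if (is.null(labels)) labels <- colnames(draws)
  if (is.null(labels)) {
    labels <- if (ncol(draws) == 0) character(0)
              else paste0("par", seq_len(ncol(draws)))
  }
  if (length(labels) == 0) {
    warning("no parameters to export")
    return(invisible(character(0)))
  }
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", dir)
  }
  files <- character(0)
  safe <- gsub("[^A-Za-z0-9._-]", "_", labels)
  for (j in seq_along(labels)) {
    f <- file.path(dir, paste0("trace_", safe[j], ".", format))
    ok <- tryCatch({
      if (format == "png") grDevices::png(f, width = 800, height = 400)
      else grDevices::pdf(f, width = 8, height = 4)
      graphics::plot(draws[, j], type = "l", xlab = "retained draw",
                     ylab = labels[j], main = paste("trace:", labels[j]))
      grDevices::dev.off()
      TRUE
    }, error = function(e) {
      try(grDevices::dev.off(), silent = TRUE)
      warning("trace plot failed for ", labels[j], ": ", conditionMessage(e))
      FALSE
    })
    if (ok) files <- c(files, f)
  }
  tidy <- file.path(dir, "draws.tsv")
  df <- as.data.frame(draws[, seq_along(labels), drop = FALSE])
  names(df) <- labels
  utils::write.table(df, tidy, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(files, tidy))
}
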