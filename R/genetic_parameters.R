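#' Derive genetic-parameter draws from (co)variance draws
#'
#' Per retained draw: `h2_i = G0_ii / (G0_ii + R0_ii)`,
#' `r_g(i,j) = G0_ij / sqrt(G0_ii G0_jj)`,
#' `r_p(i,j) = (G0_ij + R0_ij) / sqrt((G0_ii + R0_ii)(G0_jj + R0_jj))`.
#' Parameters are derived draw-wise and then summarized, never as ratios
#' of posterior means.  Draws with a zero variance component are dropped
#' with a recorded count.
#'
#' @param post a `cg_posterior` from [run_gibbs()].
#' @return a `cg_parameter_draws` list with elements `h2` (matrix, draws
#'   by traits), `r_g`, `r_p` (draws by trait pairs), `pairs` (pair
#'   index matrix) and `n_dropped`.
#' @export
derive_parameters <- function(post) {
  stopifnot(inherits(post, "cg_posterior"))
  k <- length(post$traits)
  nd <- nrow(post$G0_draws)
  gdiag <- post$G0_draws[, (seq_len(k) - 1) * k + seq_len(k), drop = FALSE]
  rdiag <- post$R0_draws[, (seq_len(k) - 1) * k + seq_len(k), drop = FALSE]
  bad <- rowSums(gdiag <= 0 | rdiag <= 0 | (gdiag + rdiag) <= 0) > 0
  n_dropped <- sum(bad)
  if (n_dropped > 0) {
    message(n_dropped, " draw(s) with a zero variance component dropped")
  }
  keep <- !bad
  gd <- gdiag[keep, , drop = FALSE]
  rd <- rdiag[keep, , drop = FALSE]
  h2 <- gd / (gd + rd)
  colnames(h2) <- paste0("h2_", post$traits)
  pairs <- if (k > 1) t(utils::combn(k, 2)) else matrix(integer(0), 0, 2)
  r_g <- r_p <- matrix(NA_real_, sum(keep), nrow(pairs))
  if (nrow(pairs)) {
    for (m in seq_len(nrow(pairs))) {
      i <- pairs[m, 1]; j <- pairs[m, 2]
      gij <- post$G0_draws[keep, (j - 1) * k + i]
      rij <- post$R0_draws[keep, (j - 1) * k + i]
      r_g[, m] <- gij / sqrt(gd[, i] * gd[, j])
      r_p[, m] <- (gij + rij) / sqrt((gd[, i] + rd[, i]) * (gd[, j] + rd[, j]))
    }
    pn <- paste0(post$traits[pairs[, 1]], "_", post$traits[pairs[, 2]])
    colnames(r_g) <- paste0("rg_", pn)
    colnames(r_p) <- paste0("rp_", pn)
  }
  structure(list(h2 = h2, r_g = r_g, r_p = r_p, pairs = pairs,
                 traits = post$traits, n_dropped = n_dropped),
            class = "cg_parameter_draws")
}

#' Trait-by-trait genetic-parameter summary grid
#'
#' Heritability summaries on the diagonal, genetic correlations above it,
#' phenotypic correlations below it; each cell a posterior summary
#' (mean, PSD, 95% HPD, ESS, HPD significance).
#'
#' @param draws a [derive_parameters()] result.
#' @param level HPD mass.
#' @return a `cg_parameter_matrix`: list with `summaries` (long
#'   data.frame) and `grid` (trait-by-trait character matrix formatted
#'   `"mean+-psd(lo:hi)"`).
#' @export
parameter_matrix <- function(draws, level = 0.95) {
  stopifnot(inherits(draws, "cg_parameter_draws"))
  k <- length(draws$traits)
  cells <- list()
  for (t in seq_len(k)) {
    cells[[length(cells) + 1]] <- cbind(
      summarize_draws(draws$h2[, t], level, colnames(draws$h2)[t]),
      row = t, col = t)
  }
  for (m in seq_len(nrow(draws$pairs))) {
    i <- draws$pairs[m, 1]; j <- draws$pairs[m, 2]
    cells[[length(cells) + 1]] <- cbind(
      summarize_draws(draws$r_g[, m], level, colnames(draws$r_g)[m]),
      row = i, col = j)
    cells[[length(cells) + 1]] <- cbind(
      summarize_draws(draws$r_p[, m], level, colnames(draws$r_p)[m]),
      row = j, col = i)
  }
  summaries <- do.call(rbind, cells)
  fmt <- sprintf("%.2f±%.2f(%.2f:%.2f)", summaries$mean, summaries$psd,
                 summaries$hpd_low, summaries$hpd_high)
  grid <- matrix("", k, k,
                 dimnames = list(paste0("parity", draws$traits),
                                 paste0("parity", draws$traits)))
  for (r in seq_len(nrow(summaries))) {
    grid[summaries$row[r], summaries$col[r]] <- fmt[r]
  }
  structure(list(summaries = summaries, grid = grid, level = level),
            class = "cg_parameter_matrix")
}

#' @export
print.cg_parameter_matrix <- function(x, ...) {
  cat("Heritabilities (diagonal), genetic correlations (above),",
      "phenotypic correlations (below):\n")
  print(x$grid, quote = FALSE)
  invisible(x)
}

#' Write the parameter grid as delimited text
#'
#' @param x a `cg_parameter_matrix`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_parameter_matrix <- function(x, path) {
  stopifnot(inherits(x, "cg_parameter_matrix"))
  utils::write.table(x$summaries[, setdiff(names(x$summaries), c("row", "col"))],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Heat-map figure of the correlation grid
#'
#' Renders genetic (above diagonal) and phenotypic (below diagonal)
#' correlations with heritabilities on the diagonal as a colour grid.
#'
#' @param x a `cg_parameter_matrix`.
#' @param path output image path (png or pdf, by extension).
#' @return `path`, invisibly.
#' @export
plot_parameter_matrix <- function(x, path) {
  stopifnot(inherits(x, "cg_parameter_matrix"))
  k <- nrow(x$grid)
  vals <- matrix(NA_real_, k, k)
  for (r in seq_len(nrow(x$summaries))) {
    vals[x$summaries$row[r], x$summaries$col[r]] <- x$summaries$mean[r]
  }
  ok <- tryCatch({
    if (grepl("[.]pdf$", path)) grDevices::pdf(path, width = 6, height = 6)
    else grDevices::png(path, width = 600, height = 600)
    pal <- grDevices::hcl.colors(41, "Blue-Red 3", rev = TRUE)
    graphics::image(seq_len(k), seq_len(k), t(vals[k:1, , drop = FALSE]),
                    zlim = c(-1, 1), col = pal, axes = FALSE,
                    xlab = "", ylab = "")
    graphics::axis(1, at = seq_len(k), labels = colnames(x$grid))
    graphics::axis(2, at = seq_len(k), labels = rev(rownames(x$grid)))
    for (i in seq_len(k)) for (j in seq_len(k)) {
      graphics::text(j, k - i + 1, sprintf("%.2f", vals[i, j]))
    }
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    warning("figure rendering failed: ", conditionMessage(e))
    FALSE
  })
  invisible(if (ok) path else NA_character_)
}
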