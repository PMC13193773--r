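#' Logistic regression of abortion status on herd risk factors
#'
#' Fits, by maximum likelihood (IRLS via [stats::glm()]), a logistic
#' model of one parity's binary abortion outcome (event = abortion = 1)
#' on categorical risk factors, with configurable reference levels.
#'
#' @param records record data.frame (doe_id, parity, outcome plus factor
#'   columns).
#' @param trait parity to analyse.
#' @param factors factor column names (default year, season, age_class).
#' @param reference_levels optional named list/vector, factor -> baseline
#'   level; default: first level in sort order.
#' @return a `cg_logistic` object: the glm `fit`, `coefficients`,
#'   `cov_matrix`, `log_likelihood`, `n_obs`, `converged`,
#'   `reference_levels`, `factors`.
#' @export
fit_logistic <- function(records, trait,
                         factors = c("year", "season", "age_class"),
                         reference_levels = NULL) {
  d <- records[records$parity == trait, , drop = FALSE]
  if (nrow(d) == 0) stop("no records for parity ", trait)
  y <- d$outcome
  if (length(unique(y)) < 2) {
    stop("outcome is constant at parity ", trait, "; logistic fit undefined")
  }
  keep <- character(0)
  for (f in factors) {
    v <- factor(as.character(d[[f]]))
    if (nlevels(v) < 2) {
      warning("factor '", f, "' has a single observed level and is dropped")
      next
    }
    ref <- if (!is.null(reference_levels) && !is.null(reference_levels[[f]])) {
      as.character(reference_levels[[f]])
    } else levels(v)[1]
    if (!ref %in% levels(v)) {
      stop("reference level '", ref, "' not observed for factor '", f, "'")
    }
    d[[f]] <- stats::relevel(v, ref = ref)
    keep <- c(keep, f)
  }
  if (!length(keep)) stop("no usable factors")
  fml <- stats::as.formula(paste("outcome ~", paste(keep, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = d, family = stats::binomial("logit"),
               control = stats::glm.control(epsilon = 1e-12, maxit = 200)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (sep_warn || !fit$converged) {
    se <- sqrt(diag(stats::vcov(fit)))
    bad <- names(se)[se > 10][1]
    stop("logistic fit did not converge (possible complete separation",
         if (!is.na(bad)) paste0(" involving ", bad), ")")
  }
  refs <- vapply(keep, function(f) levels(d[[f]])[1], character(1))
  structure(list(fit = fit,
                 coefficients = stats::coef(fit),
                 cov_matrix = stats::vcov(fit),
                 log_likelihood = as.numeric(stats::logLik(fit)),
                 n_obs = nrow(d),
                 converged = TRUE,
                 reference_levels = refs,
                 factors = keep,
                 trait = trait),
            class = "cg_logistic")
}

#' Odds ratios with Wald confidence intervals
#'
#' `OR = exp(beta)` per non-reference level with
#' `CI = exp(beta +/- z * SE)`; reference levels are reported as
#' `"Reference"`.
#'
#' @param fit a [fit_logistic()] result.
#' @param level confidence level (default 0.95).
#' @return data.frame with factor, level, or, ci_low, ci_high, reference.
#' @export
odds_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "cg_logistic"), fit$converged)
  z <- stats::qnorm(1 - (1 - level) / 2)
  beta <- fit$coefficients
  se <- sqrt(diag(fit$cov_matrix))
  rows <- list()
  for (f in fit$factors) {
    levs <- levels(fit$fit$model[[f]])
    for (l in levs) {
      nm <- paste0(f, l)
      if (l == fit$reference_levels[[f]]) {
        rows[[length(rows) + 1]] <- data.frame(
          factor = f, level = l, or = 1, ci_low = NA_real_, ci_high = NA_real_,
          reference = TRUE, stringsAsFactors = FALSE)
      } else if (nm %in% names(beta)) {
        rows[[length(rows) + 1]] <- data.frame(
          factor = f, level = l, or = exp(beta[[nm]]),
          ci_low = exp(beta[[nm]] - z * se[[nm]]),
          ci_high = exp(beta[[nm]] + z * se[[nm]]),
          reference = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Joint significance test of a factor
#'
#' Wald chi-square test that all the factor's level coefficients are zero
#' (degrees of freedom = number of non-reference levels); a
#' likelihood-ratio test is available and is the fallback when the
#' coefficient sub-covariance is singular.
#'
#' @param fit a [fit_logistic()] result.
#' @param factor factor name.
#' @param type `"wald"` (default) or `"lrt"`.
#' @return the p-value.
#' @export
factor_test <- function(fit, factor, type = c("wald", "lrt")) {
  stopifnot(inherits(fit, "cg_logistic"), fit$converged)
  type <- match.arg(type)
  if (!factor %in% fit$factors) stop("unknown factor: ", factor)
  if (type == "wald") {
    idx <- grep(paste0("^", factor), names(fit$coefficients))
    idx <- idx[names(fit$coefficients)[idx] != "(Intercept)"]
    b <- fit$coefficients[idx]
    V <- fit$cov_matrix[idx, idx, drop = FALSE]
    stat <- tryCatch(as.numeric(t(b) %*% solve(V, b)), error = function(e) NA)
    if (is.na(stat) || stat < 0) {
      warning("singular sub-covariance; falling back to the LRT")
      return(factor_test(fit, factor, "lrt"))
    }
    return(stats::pchisq(stat, df = length(b), lower.tail = FALSE))
  }
  reduced <- setdiff(fit$factors, factor)
  d <- fit$fit$model
  fml <- stats::as.formula(paste("outcome ~",
                                 if (length(reduced)) paste(reduced, collapse = " + ")
                                 else "1"))
  fit0 <- stats::glm(fml, data = d, family = stats::binomial("logit"))
  stat <- as.numeric(2 * (stats::logLik(fit$fit) - stats::logLik(fit0)))
  df <- length(fit$coefficients) - length(stats::coef(fit0))
  stats::pchisq(stat, df = df, lower.tail = FALSE)
}

#' Combined risk-factor report over traits
#'
#' One merged table across parities: rows are factor levels (references
#' marked), per-trait odds-ratio columns with confidence intervals, and a
#' per-factor joint p-value row.  Reference levels may differ by trait.
#'
#' @param records record data.frame.
#' @param traits parities to analyse (default 1:3).
#' @param factors factor columns.
#' @param reference_levels optional per-trait list of named reference
#'   levels, indexed as `reference_levels[[as.character(trait)]]`.
#' @param level confidence level.
#' @param test `"wald"` or `"lrt"`.
#' @return a `cg_risk_table`: `table` (long data.frame: trait, factor,
#'   level, or, ci_low, ci_high, reference, p_value), `fits`, `failed`.
#' @export
risk_table <- function(records, traits = 1:3,
                       factors = c("year", "season", "age_class"),
                       reference_levels = NULL, level = 0.95,
                       test = c("wald", "lrt")) {
  test <- match.arg(test)
  fits <- list()
  failed <- list()
  rows <- list()
  for (tt in traits) {
    refs <- if (!is.null(reference_levels)) reference_levels[[as.character(tt)]]
    res <- tryCatch(fit_logistic(records, tt, factors, refs),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed[[as.character(tt)]] <- conditionMessage(res)
      next
    }
    fits[[as.character(tt)]] <- res
    ors <- odds_ratios(res, level)
    ors$trait <- tt
    ors$p_value <- NA_real_
    for (f in res$factors) {
      ors$p_value[match(f, ors$factor)] <- factor_test(res, f, test)
    }
    rows[[length(rows) + 1]] <- ors
  }
  if (!length(rows)) stop("no converged fits")
  tab <- do.call(rbind, rows)
  tab <- tab[, c("trait", "factor", "level", "or", "ci_low", "ci_high",
                 "reference", "p_value")]
  structure(list(table = tab, fits = fits, failed = failed, level = level),
            class = "cg_risk_table")
}

#' @export
print.cg_risk_table <- function(x, ...) {
  cat("<cg_risk_table> odds ratios (event = abortion)\n")
  t2 <- x$table
  t2$or_ci <- ifelse(t2$reference, "Reference",
                     sprintf("%.2f(%.2f-%.2f)", t2$or, t2$ci_low, t2$ci_high))
  print(t2[, c("trait", "factor", "level", "or_ci", "p_value")],
        row.names = FALSE, digits = 3)
  if (length(x$failed)) {
    for (tt in names(x$failed)) {
      cat("parity ", tt, ": fit failed (", x$failed[[tt]], ")\n", sep = "")
    }
  }
  invisible(x)
}

#' Write the risk-factor report
#'
#' @param x a `cg_risk_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_risk_table <- function(x, path) {
  stopifnot(inherits(x, "cg_risk_table"))
  utils::write.table(x$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a written risk-factor report
#'
#' @param path file written by [write_risk_table()].
#' @return the report data.frame.
#' @export
read_risk_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
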