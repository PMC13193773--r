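#' Doe-stratified k-fold split
#'
#' Partitions does (not records) into k folds of sizes differing by at
#' most one, so all of a doe's parities stay in one fold.
#'
#' @param records record data.frame with a `doe_id` column.
#' @param k number of folds (default 5; `k = 2` emulates an equal
#'   train/test split).
#' @param seed integer seed (`NULL` = current RNG state).
#' @return named integer vector: fold assignment per doe.
#' @export
kfold_split <- function(records, k = 5, seed = NULL) {
  does <- sort(unique(records$doe_id))
  if (k < 2) stop("k must be >= 2")
  if (k > length(does)) {
    stop("k = ", k, " exceeds the number of does (", length(does), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  perm <- sample(does)
  folds <- rep(seq_len(k), length.out = length(does))
  stats::setNames(folds, perm)[does]
}

#' Predict held-out records from a training fit
#'
#' Point predictions from training posterior means: fixed part `x'b` from
#' the matched factor-level coefficients (a level unseen in training
#' contributes 0 with a warning), plus a breeding value propagated through
#' the pedigree as `0.5 (a_sire + a_dam)` of the training posterior means
#' (a doe with a training record uses her own posterior mean; unknown
#' parents contribute 0).  Threshold models return the abortion
#' probability `pnorm(x'b + a)`; linear models the linear predictor.
#'
#' @param fit a `cg_posterior` from [run_gibbs()].
#' @param test_records record data.frame to predict.
#' @param ped the [pedigree()] used in the fit.
#' @param train_does character vector of does whose records were in
#'   training (their own posterior means are used directly).
#' @return numeric predictions, one per test record.
#' @export
predict_held_out <- function(fit, test_records, ped, train_does = character(0)) {
  stopifnot(inherits(fit, "cg_posterior"), inherits(ped, "cg_pedigree"))
  k <- length(fit$traits)
  pred <- rep(NA_real_, nrow(test_records))
  unseen <- character(0)
  a_hat <- fit$a_mean
  idx <- ped$index
  for (t in seq_len(k)) {
    parity_t <- fit$traits[t]
    sel <- which(test_records$parity == parity_t)
    if (!length(sel)) next
    b <- fit$b_mean[[t]]
    levels_t <- fit$factor_levels[[t]]
    xb <- numeric(length(sel))
    if ("(intercept)" %in% names(b)) xb <- xb + b[["(intercept)"]]
    for (f in names(levels_t)) {
      val <- as.character(test_records[[f]][sel])
      lab <- paste0(f, ":", val)
      coefs <- ifelse(lab %in% names(b), b[lab], 0)
      bad <- !(val %in% levels_t[[f]])
      if (any(bad)) unseen <- union(unseen, unique(lab[bad]))
      xb <- xb + ifelse(is.na(coefs), 0, coefs)
    }
    doe <- as.character(test_records$doe_id[sel])
    di <- idx[doe]
    own <- doe %in% train_does
    s <- ped$sire_idx[di]
    d <- ped$dam_idx[di]
    pa <- 0.5 * ifelse(is.na(s), 0, a_hat[ifelse(is.na(s), 1, s), t]) +
          0.5 * ifelse(is.na(d), 0, a_hat[ifelse(is.na(d), 1, d), t])
    ahat <- ifelse(own, a_hat[di, t], pa)
    eta <- xb + ahat
    pred[sel] <- if (fit$spec$scale == "threshold") stats::pnorm(eta) else eta
  }
  if (length(unseen)) {
    warning("factor level(s) unseen in training predicted as 0: ",
            paste(utils::head(unseen, 5), collapse = ", "))
  }
  pred
}

#' Predictive ability: Pearson correlation with significance
#'
#' Sample Pearson correlation between observed and predicted values and
#' the two-sided p-value from `t = r sqrt((n - 2) / (1 - r^2))` on
#' `n - 2` degrees of freedom.
#'
#' @param observed,predicted numeric vectors of equal length (>= 3).
#' @return list with `r`, `p_value`, `n`.
#' @export
predictive_ability <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 3)
  if (stats::sd(observed) == 0 || stats::sd(predicted) == 0) {
    stop("undefined correlation: zero variance on one side")
  }
  n <- length(observed)
  r <- sum((observed - mean(observed)) * (predicted - mean(predicted))) /
    ((n - 1) * stats::sd(observed) * stats::sd(predicted))
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1) return(list(r = r, p_value = 0, n = n))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p_value = 2 * stats::pt(-abs(tstat), df = n - 2), n = n)
}

.cv_variants <- function() {
  list(
    `linear-univariate` = list(scale = "linear", multivariate = FALSE),
    `threshold-univariate` = list(scale = "threshold", multivariate = FALSE),
    `linear-multivariate` = list(scale = "linear", multivariate = TRUE),
    `threshold-multivariate` = list(scale = "threshold", multivariate = TRUE)
  )
}

#' Cross-validated comparison of the four model variants
#'
#' Runs linear/threshold x univariate/multivariate animal models over
#' shared doe-stratified folds, predicting each held-out doe's records
#' from the training posterior means, and ranks variants by mean
#' cross-validated Pearson correlation.  Chain seeds depend only on the
#' fold and the variant's content, so identical variants reproduce
#' identical results.
#'
#' @param records record data.frame.
#' @param ped a [pedigree()].
#' @param variants named list of variants (`scale`, `multivariate`);
#'   default all four.
#' @param k number of folds.
#' @param chain_cfg a [gibbs_config()] for the CV chains; default reduced
#'   settings (20,000 iterations, 2,000 burn-in, thinning 20).
#' @param seed integer seed controlling folds and chains.
#' @param traits parities to include.
#' @return a `cg_cv_result`: `table` (variant x trait rows: mean_r,
#'   p_value, n_folds), `per_fold` (long data.frame), `ranking`
#'   (variants by mean r, best first), `folds`, `failed`.
#' @export
compare_models <- function(records, ped, variants = .cv_variants(), k = 5,
                           chain_cfg = gibbs_config(20000, 2000, 20),
                           seed = 1L, traits = sort(unique(records$parity))) {
  folds <- kfold_split(records, k = k, seed = seed)
  per_fold <- list()
  failed <- character(0)
  for (vn in names(variants)) {
    v <- variants[[vn]]
    for (fold in seq_len(k)) {
      test_does <- names(folds)[folds == fold]
      train <- records[!(records$doe_id %in% test_does), , drop = FALSE]
      test <- records[records$doe_id %in% test_does, , drop = FALSE]
      res <- tryCatch({
        if (v$multivariate) {
          spec <- model_spec(traits = traits, scale = v$scale)
          cfg <- chain_cfg
          cfg$seed <- .cv_seed(seed, fold, v$scale, TRUE, 0)
          fit <- run_gibbs(train, ped, spec, cfg)
          pred <- predict_held_out(fit, test, ped)
          lapply(traits, function(tt) {
            sel <- test$parity == tt
            pa <- predictive_ability(test$outcome[sel], pred[sel])
            data.frame(model = vn, trait = tt, fold = fold, r = pa$r,
                       n = pa$n, stringsAsFactors = FALSE)
          })
        } else {
          lapply(traits, function(tt) {
            spec <- model_spec(traits = tt, scale = v$scale)
            cfg <- chain_cfg
            cfg$seed <- .cv_seed(seed, fold, v$scale, FALSE, tt)
            fit <- run_gibbs(train[train$parity == tt, , drop = FALSE],
                             ped, spec, cfg)
            sel <- test$parity == tt
            pred <- predict_held_out(fit, test[sel, , drop = FALSE], ped)
            pa <- predictive_ability(test$outcome[sel], pred)
            data.frame(model = vn, trait = tt, fold = fold, r = pa$r,
                       n = pa$n, stringsAsFactors = FALSE)
          })
        }
      }, error = function(e) {
        warning("variant '", vn, "' failed in fold ", fold, ": ",
                conditionMessage(e))
        NULL
      })
      if (is.null(res)) {
        failed <- union(failed, vn)
      } else {
        per_fold <- c(per_fold, res)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)
  if (is.null(per_fold) || nrow(per_fold) == 0) {
    stop("every model variant failed in every fold; see warnings")
  }
  tab <- do.call(rbind, lapply(split(per_fold, list(per_fold$model, per_fold$trait),
                                     drop = TRUE), function(d) {
    z <- atanh(pmin(pmax(d$r, -0.999999), 0.999999))
    p <- if (length(z) >= 2 && stats::sd(z) > 0) {
      stats::t.test(z)$p.value
    } else NA_real_
    data.frame(model = d$model[1], trait = d$trait[1],
               mean_r = mean(d$r), p_value = p, n_folds = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(tab) <- NULL
  rank_tab <- vapply(split(tab$mean_r, tab$model), mean, numeric(1))
  ranking <- names(sort(rank_tab, decreasing = TRUE))
  tab <- tab[order(match(tab$model, ranking), tab$trait), ]
  structure(list(table = tab, per_fold = per_fold, ranking = ranking,
                 folds = folds, failed = failed, k = k, seed = seed),
            class = "cg_cv_result")
}

## chain seed depends only on fold and variant content (scale,
## multivariate, trait) so identical variants get identical chains
.cv_seed <- function(base, fold, scale, multivariate, trait) {
  x <- abs(as.numeric(base)) * 977 + fold * 1009 +
    (scale == "threshold") * 101 + multivariate * 11 + trait * 7
  as.integer(x %% (.Machine$integer.max - 1))
}

#' @export
print.cg_cv_result <- function(x, ...) {
  cat("<cg_cv_result> ", x$k, "-fold CV, ranking: ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  print(x$table, row.names = FALSE, digits = 3)
  if (length(x$failed)) cat("failed variants:", paste(x$failed, collapse = ", "), "\n")
  invisible(x)
}

#' Write the CV comparison table
#'
#' @param x a `cg_cv_result`.
#' @param path output TSV path; per-fold detail goes to
#'   `paste0(path, ".folds.tsv")`.
#' @return `path`, invisibly.
#' @export
write_cv_table <- function(x, path) {
  stopifnot(inherits(x, "cg_cv_result"))
  utils::write.table(x$table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(x$per_fold, paste0(path, ".folds.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
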