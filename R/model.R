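#' Model specification for the animal model
#'
#' Declares the trait set (parities), the trait scale, fixed factors and
#' variance priors.  The only random term is the additive-genetic (animal)
#' effect with covariance `A %x% G0`.  For threshold traits the threshold
#' is fixed at 0 and the residual variance pinned to 1 (liability-scale
#' identifiability); fixed-effect coefficients carry flat priors.
#'
#' @param traits integer vector of parities to model (default 1:3).
#' @param scale `"threshold"` (liability model for the binary outcome) or
#'   `"linear"` (the 0/1 outcome treated as Gaussian).
#' @param factors fixed factors, a subset of
#'   `c("year", "season", "age_class")`; `character(0)` fits no fixed
#'   part at all (a factor whose observed levels all collapse is replaced
#'   by a plain intercept).
#' @param nu_a,S_a inverse-Wishart prior degrees of freedom and scale for
#'   G0 in the centered parameterization.  Linear models default to the
#'   flat-equivalent (improper) `nu_a = -(n_traits + 1)`, `S_a = 0`;
#'   threshold models to the weakly informative proper
#'   `nu_a = n_traits + 2`, `S_a = 0.2 I` (the identified threshold
#'   posterior requires a proper genetic prior).
#' @param nu_e,S_e likewise for R0; used by linear models (threshold
#'   models hold unit residual variances and sample the residual
#'   correlations under a uniform prior).
#' @param genetic if `FALSE`, the animal term is dropped (used for
#'   degenerate-limit checks); G0 is then held at zero.
#' @param parameterization `"noncentered"` (genetic covariance carried by
#'   its Cholesky factor with standardized breeding values, plus an
#'   interweaved centered Metropolis redraw of the factor; the default
#'   for threshold traits, where it avoids the near-zero sticking of the
#'   centered sampler) or `"centered"` (breeding values on their natural
#'   scale with the conjugate inverse-Wishart G0 draw; the default for
#'   linear traits).
#' @param lambda_tau2 prior scale for the genetic Cholesky factor in the
#'   non-centered parameterization: row `u` elements are
#'   `N(0, lambda_tau2 / u)`, so each trait's genetic variance has prior
#'   scale `lambda_tau2` regardless of trait order.
#' @return a `cg_model_spec` list.
#' @export
model_spec <- function(traits = 1:3,
                       scale = c("threshold", "linear"),
                       factors = c("year", "season", "age_class"),
                       nu_a = NULL, S_a = NULL, nu_e = NULL, S_e = NULL,
                       genetic = TRUE,
                       parameterization = NULL, lambda_tau2 = 0.5) {
  scale <- match.arg(scale)
  if (is.null(parameterization)) {
    parameterization <- if (scale == "threshold") "noncentered" else "centered"
  }
  parameterization <- match.arg(parameterization, c("centered", "noncentered"))
  traits <- sort(unique(as.integer(traits)))
  stopifnot(length(traits) >= 1)
  k <- length(traits)
  ## threshold traits: the liability scale carries no information from the
  ## data, so improper flat priors on the covariances leave the working
  ## posterior improper and the chain drifts; both variance priors default
  ## to weakly informative proper inverse Wisharts there.  Linear models
  ## keep the flat-equivalent defaults.
  if (is.null(nu_a)) nu_a <- if (scale == "threshold") k + 2 else -(k + 1)
  if (is.null(S_a)) {
    S_a <- if (scale == "threshold") diag(0.2, k) else matrix(0, k, k)
  }
  ## threshold traits: the working liability scale is unidentified by the
  ## data, so the residual prior must be proper to anchor it; IW(k + 1, I)
  ## induces marginally uniform residual correlations.  Linear models keep
  ## the flat-equivalent default.
  if (is.null(nu_e)) nu_e <- if (scale == "threshold") k + 1 else -(k + 1)
  if (is.null(S_e)) S_e <- if (scale == "threshold") diag(1, k) else matrix(0, k, k)
  structure(list(traits = traits, scale = scale, factors = factors,
                 nu_a = nu_a, S_a = S_a, nu_e = nu_e, S_e = S_e,
                 genetic = genetic, parameterization = parameterization,
                 lambda_tau2 = lambda_tau2),
            class = "cg_model_spec")
}

#' Gibbs-chain configuration
#'
#' Defaults follow the single-chain protocol of 200,000 iterations with a
#' 20,000-iteration burn-in and thinning interval 100, retaining exactly
#' 1,800 draws.
#'
#' @param n_iter total iterations.
#' @param burn_in iterations discarded before retention starts.
#' @param thin thinning interval.
#' @param seed integer seed (`NULL` = use the current RNG state).
#' @param start_g0,start_r0 optional start values for G0 and R0.
#' @param fix_g0,fix_r0 hold the corresponding covariance fixed at its
#'   start value (degenerate-limit checks).
#' @param verbose print progress every 1,000 iterations.
#' @return a `cg_gibbs_config` list.
#' @export
gibbs_config <- function(n_iter = 200000L, burn_in = 20000L, thin = 100L,
                         seed = NULL, start_g0 = NULL, start_r0 = NULL,
                         fix_g0 = FALSE, fix_r0 = FALSE, verbose = FALSE) {
  stopifnot(n_iter > burn_in, thin >= 1)
  n_keep <- (n_iter - burn_in) %/% thin
  if (n_keep < 2) stop("configuration retains fewer than 2 draws")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_keep = as.integer(n_keep),
                 seed = seed, start_g0 = start_g0, start_r0 = start_r0,
                 fix_g0 = fix_g0, fix_r0 = fix_r0, verbose = verbose),
            class = "cg_gibbs_config")
}

#' Build the mixed-model design structure
#'
#' Indexes records against the pedigree and the fixed factors: per-trait
#' incidence maps from records to fixed-effect columns (the first factor is
#' coded with all its observed levels, later factors drop their reference
#' level, so the fixed part is full rank), and breeding-value slots for
#' every pedigree animal.  Factor levels observed zero times for a trait
#' are dropped with a warning; a factor left with fewer than 2 observed
#' levels is dropped entirely.
#'
#' @param records data.frame with columns doe_id, parity, outcome and the
#'   factor columns named in `spec$factors`.
#' @param ped a [pedigree()] covering every recorded doe.
#' @param spec a [model_spec()].
#' @return a `cg_mme_structure` list consumed by [run_gibbs()].
#' @export
build_mme_structure <- function(records, ped, spec) {
  stopifnot(inherits(ped, "cg_pedigree"), inherits(spec, "cg_model_spec"))
  if (nrow(records) == 0) stop("no records")
  records <- records[records$parity %in% spec$traits, , drop = FALSE]
  if (nrow(records) == 0) stop("no records for the requested traits")
  missing_doe <- setdiff(unique(records$doe_id), ped$animal)
  if (length(missing_doe)) {
    stop("doe absent from pedigree: ", missing_doe[1])
  }
  k <- length(spec$traits)
  does <- sort(unique(records$doe_id))
  n <- length(does)
  doe_pos <- stats::setNames(seq_len(n), does)

  Y <- matrix(NA_real_, n, k)
  for (t in seq_len(k)) {
    rt <- records[records$parity == spec$traits[t], ]
    if (anyDuplicated(rt$doe_id)) {
      stop("duplicate record for doe ", rt$doe_id[anyDuplicated(rt$doe_id)],
           " at parity ", spec$traits[t])
    }
    Y[doe_pos[rt$doe_id], t] <- rt$outcome
  }
  miss <- is.na(Y)
  threshold <- rep(as.integer(spec$scale == "threshold"), k)
  if (spec$scale == "threshold") {
    for (t in seq_len(k)) {
      obs <- Y[!miss[, t], t]
      if (length(unique(obs)) < 2) {
        stop("separation: parity ", spec$traits[t],
             " has a single outcome class; the liability is unidentifiable")
      }
    }
  }

  ## per-trait fixed-effect column maps
  col_labels <- colptr <- colrows <- factor_levels <- vector("list", k)
  for (t in seq_len(k)) {
    rt <- records[records$parity == spec$traits[t], ]
    rows <- unname(doe_pos[rt$doe_id])
    labels <- character(0)
    rec_cols <- vector("list", 0)
    flev <- list()
    first_factor <- TRUE
    for (f in spec$factors) {
      lev <- sort(unique(as.character(rt[[f]])))
      flev[[f]] <- lev
      if (length(lev) < 2) {
        warning("factor '", f, "' has fewer than 2 observed levels at parity ",
                spec$traits[t], " and is dropped")
        if (first_factor && length(lev) == 1) {
          ## keep it as the intercept-bearing column
          labels <- c(labels, paste0(f, ":", lev))
          rec_cols <- c(rec_cols, list(rep(length(labels), nrow(rt))))
          first_factor <- FALSE
        }
        next
      }
      use <- if (first_factor) lev else lev[-1]
      idx <- match(as.character(rt[[f]]), use)          # NA for reference
      idx[!is.na(idx)] <- idx[!is.na(idx)] + length(labels)
      labels <- c(labels, paste0(f, ":", use))
      rec_cols <- c(rec_cols, list(ifelse(is.na(idx), 0L, idx)))
      first_factor <- FALSE
    }
    ## a factor list that was requested but fully dropped still needs an
    ## intercept column; an explicitly empty factor list means no fixed part
    if (length(labels) == 0 && length(spec$factors) > 0) {
      labels <- "(intercept)"
      rec_cols <- list(rep(1L, nrow(rt)))
    }
    p <- length(labels)
    ## CSC over columns: for each column the 0-based doe rows
    cptr <- integer(p + 1)
    crow_list <- vector("list", p)
    for (j in seq_len(p)) {
      sel <- Reduce(`|`, lapply(rec_cols, function(v) v == j))
      crow_list[[j]] <- rows[sel] - 1L
      cptr[j + 1] <- cptr[j] + sum(sel)
    }
    col_labels[[t]] <- labels
    colptr[[t]] <- cptr
    colrows[[t]] <- as.integer(unlist(crow_list))
    factor_levels[[t]] <- flev
  }

  Ainv <- relationship_inverse(ped)
  Acsc <- methods::as(methods::as(Ainv, "generalMatrix"), "CsparseMatrix")
  q <- length(ped$animal)
  animal_doe <- rep(-1L, q)
  present <- match(does, ped$animal)
  animal_doe[present] <- seq_len(n) - 1L

  structure(list(
    n = n, n_traits = k, q = q,
    Y = ifelse(miss, 0, Y), miss = matrix(as.integer(miss), n, k),
    threshold = threshold,
    colptr = colptr, colrows = colrows, col_labels = col_labels,
    factor_levels = factor_levels,
    animal_doe = animal_doe,
    doe_ids = does,
    ainv_rowptr = Acsc@p, ainv_colind = Acsc@i, ainv_vals = Acsc@x,
    nu_a = spec$nu_a, S_a = spec$S_a, nu_e = spec$nu_e, S_e = spec$S_e,
    spec = spec, animals = ped$animal,
    sire_idx = ped$sire_idx, dam_idx = ped$dam_idx
  ), class = "cg_mme_structure")
}

#' Initialize the Gibbs state
#'
#' Observed linear outcomes enter as fixed liabilities; observed threshold
#' outcomes start at +/-0.5 on the correct side of the zero threshold;
#' missing entries start at 0.  Location effects start at 0.
#'
#' @param str a [build_mme_structure()] result.
#' @param G0,R0 start covariance matrices (defaults: `0.2 I` and `I`).
#' @return a state list (`L`, `E`, `a`, `b`, `G0`, `R0`).
#' @export
init_state <- function(str, G0 = NULL, R0 = NULL) {
  k <- str$n_traits
  if (is.null(G0)) G0 <- diag(0.2, k)
  if (is.null(R0)) R0 <- diag(1, k)
  L <- str$Y
  for (t in seq_len(k)) {
    if (str$threshold[t] == 1) {
      L[, t] <- ifelse(str$miss[, t] == 1, 0, ifelse(str$Y[, t] > 0.5, 0.5, -0.5))
    } else {
      L[, t] <- ifelse(str$miss[, t] == 1, 0, str$Y[, t])
    }
  }
  b <- lapply(str$col_labels, function(lab) numeric(length(lab)))
  list(L = L, E = L, a = matrix(0, str$q, k), b = b,
       G0 = G0, R0 = R0)
}

#' One liability sweep
#'
#' Draws each latent liability from its full conditional: truncated at the
#' zero threshold by the observed binary outcome, untruncated for missing
#' entries (data augmentation), with conditional mean and variance from the
#' doe's other traits through `R0`.  Observed linear entries are left
#' untouched.
#'
#' @param state,str current Gibbs state and model structure.
#' @return updated state.
#' @export
sample_liabilities <- function(state, str) {
  out <- .cg_step_liab(state, str)
  state[c("L", "E")] <- out[c("L", "E")]
  state
}

#' One location sweep (fixed effects, then breeding values)
#'
#' Scalar (single-site) Gibbs draws from each effect's Gaussian full
#' conditional; breeding values use the sparse A-inverse contributions and
#' the current G0 inverse, swept in pedigree order.
#'
#' @param state,str current Gibbs state and model structure.
#' @return updated state.
#' @export
sample_location <- function(state, str) {
  out <- .cg_step_location(state, str, str$spec$genetic)
  state[c("b", "a", "E")] <- out[c("b", "a", "E")]
  state
}

#' Draw the genetic covariance G0
#'
#' Inverse-Wishart full conditional with degrees `nu_a + q` and scale
#' `S_a + M`, `M[j, k] = a_j' A^{-1} a_k`.
#'
#' @param state,str current Gibbs state and model structure.
#' @return updated state with a new `G0`.
#' @export
sample_G0 <- function(state, str) {
  state$G0 <- .cg_step_G0(state, str)
  state
}

#' Draw the residual covariance R0
#'
#' Inverse-Wishart full conditional on the residual cross-products.  With
#' `rescale = TRUE` the state is afterwards mapped onto the identified
#' liability scale: rows and columns rescaled so every threshold-trait
#' residual variance is exactly 1 (correlation-preserving), with the
#' rescale propagated to liabilities, location effects and G0.  The chain
#' driver keeps the working scale and applies this identification map only
#' to retained draws.
#'
#' @param state,str current Gibbs state and model structure.
#' @param rescale apply the threshold-trait unit-diagonal identification.
#' @return updated state.
#' @export
sample_R0 <- function(state, str, rescale = TRUE) {
  out <- .cg_step_R0(state, str, rescale)
  state[c("L", "E", "a", "b", "G0", "R0")] <-
    out[c("L", "E", "a", "b", "G0", "R0")]
  state
}

#' Run the Gibbs sampler
#'
#' Full sweeps in the order liabilities, fixed effects, breeding values
#' (pedigree order), G0, R0; every `thin`-th draw after `burn_in` is
#' retained.  Under the default chain settings exactly
#' `(200000 - 20000) / 100 = 1800` draws are kept.
#'
#' @param records data.frame of trait records (see
#'   [build_mme_structure()]), or an already-built `cg_mme_structure`.
#' @param ped a [pedigree()] (ignored when `records` is a structure).
#' @param spec a [model_spec()] (ignored when `records` is a structure).
#' @param cfg a [gibbs_config()].
#' @return a `cg_posterior` object: `G0_draws`, `R0_draws` (matrices with
#'   one row per retained draw, columns the vectorised trait-by-trait
#'   matrices), posterior-mean location effects `b_mean` (named, per
#'   trait) and `a_mean` (animals by traits), plus metadata.
#' @export
run_gibbs <- function(records, ped = NULL, spec = model_spec(), cfg = gibbs_config()) {
  str <- if (inherits(records, "cg_mme_structure")) records
         else build_mme_structure(records, ped, spec)
  stopifnot(inherits(cfg, "cg_gibbs_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  k <- str$n_traits
  G0 <- if (!is.null(cfg$start_g0)) cfg$start_g0
        else if (!str$spec$genetic) matrix(0, k, k) else diag(0.2, k)
  R0 <- if (!is.null(cfg$start_r0)) cfg$start_r0 else diag(1, k)
  init <- init_state(str, G0 = G0, R0 = R0)
  fix_g0 <- cfg$fix_g0 || !str$spec$genetic
  noncentered <- identical(str$spec$parameterization, "noncentered")
  t0 <- proc.time()[["elapsed"]]
  raw <- .cg_run_gibbs(str, init, cfg$n_iter, cfg$burn_in, cfg$thin,
                       fix_g0, cfg$fix_r0, noncentered,
                       str$spec$lambda_tau2, cfg$verbose)
  elapsed <- proc.time()[["elapsed"]] - t0
  b_mean <- lapply(seq_len(k), function(t) {
    stats::setNames(as.numeric(raw$b_mean[[t]]), str$col_labels[[t]])
  })
  names(b_mean) <- paste0("parity", str$spec$traits)
  a_mean <- raw$a_mean
  rownames(a_mean) <- str$animals
  structure(list(
    G0_draws = raw$G0_draws, R0_draws = raw$R0_draws,
    b_mean = b_mean, a_mean = a_mean,
    n_kept = raw$n_kept, spec = str$spec, cfg = cfg,
    traits = str$spec$traits, col_labels = str$col_labels,
    factor_levels = str$factor_levels,
    elapsed = elapsed
  ), class = "cg_posterior")
}

#' @export
print.cg_posterior <- function(x, ...) {
  k <- length(x$traits)
  cat("<cg_posterior> ", x$n_kept, " retained draws, ", k, " trait(s), ",
      x$spec$scale, " scale (", sprintf("%.1f", x$elapsed), "s)\n", sep = "")
  g <- matrix(colMeans(x$G0_draws), k, k)
  r <- matrix(colMeans(x$R0_draws), k, k)
  cat("posterior mean G0 diagonal:", sprintf("%.4f", diag(g)), "\n")
  cat("posterior mean R0 diagonal:", sprintf("%.4f", diag(r)), "\n")
  invisible(x)
}

#' Write retained draws as delimited text
#'
#' One row per retained draw with flattened G0 and R0 entries plus derived
#' heritabilities, and a run-metadata YAML beside it.
#'
#' @param post a `cg_posterior`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(post, path) {
  stopifnot(inherits(post, "cg_posterior"))
  k <- length(post$traits)
  gn <- outer(post$traits, post$traits, function(i, j) paste0("G0_", i, "_", j))
  rn <- outer(post$traits, post$traits, function(i, j) paste0("R0_", i, "_", j))
  df <- data.frame(post$G0_draws, post$R0_draws)
  names(df) <- c(as.vector(gn), as.vector(rn))
  for (t in seq_len(k)) {
    df[[paste0("h2_", post$traits[t])]] <-
      post$G0_draws[, (t - 1) * k + t] /
      (post$G0_draws[, (t - 1) * k + t] + post$R0_draws[, (t - 1) * k + t])
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(n_iter = post$cfg$n_iter, burn_in = post$cfg$burn_in,
               thin = post$cfg$thin, n_kept = post$n_kept,
               seed = if (is.null(post$cfg$seed)) NA else post$cfg$seed,
               scale = post$spec$scale, traits = post$traits,
               elapsed_seconds = round(post$elapsed, 2))
  yaml::write_yaml(meta, paste0(path, ".meta.yml"))
  invisible(path)
}
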