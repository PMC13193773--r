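#' Default genetic covariance matrix on the liability scale
#'
#' Built from per-trait liability heritabilities and genetic correlations,
#' assuming unit residual variances (threshold identifiability), so
#' `G0[t, t] = h2[t] / (1 - h2[t])`.
#'
#' @param h2 per-trait liability heritabilities.
#' @param r_g genetic correlations for trait pairs in column order
#'   (1-2, 1-3, 2-3 for three traits).
#' @return symmetric positive semi-definite matrix.
#' @export
make_g0 <- function(h2 = c(0.25, 0.11, 0.19), r_g = c(0.23, 0.29, 0.48)) {
  v <- h2 / (1 - h2)
  k <- length(v)
  G <- diag(v, k)
  if (k > 1) {
    G[lower.tri(G)] <- r_g * sqrt(tcrossprod(v))[lower.tri(G)]
    G[upper.tri(G)] <- t(G)[upper.tri(G)]
  }
  .check_psd(G, "G0")
  G
}

#' Default residual covariance matrix on the liability scale
#'
#' Unit diagonals (threshold identifiability); off-diagonals chosen so
#' the implied phenotypic correlations `(G0_ij + R0_ij) /
#' sqrt((G0_ii + 1) (G0_jj + 1))` match `r_p`.
#'
#' @param G0 genetic covariance matrix.
#' @param r_p target phenotypic correlations for trait pairs (column order).
#' @return symmetric positive semi-definite matrix with unit diagonal.
#' @export
make_r0 <- function(G0 = make_g0(), r_p = c(0.09, -0.07, 0.14)) {
  k <- nrow(G0)
  R <- diag(1, k)
  if (k > 1) {
    tot <- diag(G0) + 1
    target <- r_p * sqrt(tcrossprod(tot))[lower.tri(R)]
    R[lower.tri(R)] <- target - G0[lower.tri(G0)]
    R[upper.tri(R)] <- t(R)[upper.tri(R)]
  }
  .check_psd(R, "R0")
  R
}

.check_psd <- function(M, name) {
  if (!isSymmetric(unname(M), tol = 1e-8)) stop(name, " must be symmetric")
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop(name, " is not positive semi-definite (min eigenvalue ", min(ev), ")")
  }
  invisible(TRUE)
}

#' Simulation configuration for a synthetic dairy-goat herd
#'
#' Defaults emulate an intensively managed herd: ~3,400 founders expanded
#' over 4 offspring generations to ~35,000 animals, a mating ratio of 15
#' does per buck, about 4,000 recorded does with declining parity counts,
#' abortion incidences around 0.15/0.18/0.15, and liability-scale genetic
#' parameters h2 = (0.25, 0.11, 0.19), r_g = (0.23, 0.29, 0.48).
#'
#' @param n_founder_sires,n_founder_dams founder counts.
#' @param n_generations offspring generations.
#' @param offspring_per_gen matings (one offspring each) per generation.
#' @param does_per_buck harem size (mating ratio).
#' @param sire_carryover fraction of a generation's bucks reused from the
#'   previous generation's buck pool.
#' @param related_mating probability a harem is served by a paternal
#'   half-sib of its does, emulating within-herd family clustering that
#'   produces a realistic share of inbred animals.
#' @param n_recorded_does number of does given parity-1 records (drawn from
#'   the last two offspring generations).
#' @param G0,R0 trait-by-trait genetic and residual covariances on the
#'   liability scale (`R0` must have unit diagonal for threshold traits).
#' @param incidence per-parity target abortion incidences.
#' @param retention per-parity cumulative record-retention probabilities
#'   (monotone non-increasing; a doe recorded at parity t was recorded at
#'   all earlier parities).
#' @param year_effects,season_effects,age_effects fixed-effect sizes on the
#'   liability scale (7 years, 2 seasons, 4 age classes; first level is
#'   the baseline).
#' @param seed integer seed used by [simulate_dataset()].
#' @return a `cg_sim_config` list.
#' @export
sim_config <- function(n_founder_sires = 180,
                       n_founder_dams = 3180,
                       n_generations = 4,
                       offspring_per_gen = 7900,
                       does_per_buck = 15,
                       sire_carryover = 0.5,
                       related_mating = 0.07,
                       n_recorded_does = 3974,
                       G0 = make_g0(),
                       R0 = make_r0(),
                       incidence = c(0.15, 0.18, 0.15),
                       retention = c(1, 3247 / 3974, 2370 / 3974),
                       year_effects = c(0, 0.35, 0.25, 0.2, 0.1, 0.05, 0.15),
                       season_effects = c(0, -0.12),
                       age_effects = c(0, -0.45, -0.6, -0.65),
                       seed = 20260101L) {
  stopifnot(n_founder_sires > 0, n_founder_dams > 0, n_generations > 0,
            does_per_buck >= 1, all(incidence > 0 & incidence < 1),
            all(diff(retention) <= 1e-12), retention[1] <= 1,
            nrow(G0) == length(incidence), nrow(R0) == nrow(G0))
  .check_psd(G0, "G0")
  .check_psd(R0, "R0")
  structure(as.list(environment()), class = "cg_sim_config")
}

#' Simulate a multi-generation pedigree
#'
#' Founders are unrelated; each later generation mates a pool of dams to
#' bucks in harems of about `does_per_buck` does.  Harems are grouped by
#' the does' sire families and, with probability `related_mating`, served
#' by a paternal half-sib buck, so a share of offspring is inbred.
#'
#' @param cfg a [sim_config()].
#' @return a [pedigree()] object with attributes `sex` (per-animal
#'   `"M"`/`"F"`) and `generation` (0 = founder).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "cg_sim_config"))
  n_s <- cfg$n_founder_sires
  n_d <- cfg$n_founder_dams
  ids <- paste0("F", seq_len(n_s + n_d))
  sex <- c(rep("M", n_s), rep("F", n_d))
  gen <- rep(0L, n_s + n_d)
  sire <- rep(NA_character_, n_s + n_d)
  dam <- rep(NA_character_, n_s + n_d)
  sire_of <- rep(NA_character_, n_s + n_d)   # paternal family of each animal

  prev_bucks <- ids[sex == "M"]
  counter <- 0L
  for (g in seq_len(cfg$n_generations)) {
    females <- ids[sex == "F"]
    n_mat <- min(cfg$offspring_per_gen, length(females))
    dams_g <- sample(females, n_mat)
    ## group dams into harems by paternal family
    fam <- sire_of[match(dams_g, ids)]
    dams_g <- dams_g[order(fam, method = "radix", na.last = TRUE)]
    n_harem <- ceiling(n_mat / cfg$does_per_buck)
    males <- ids[sex == "M"]
    n_keep <- min(length(prev_bucks), round(cfg$sire_carryover * n_harem))
    pool <- c(if (n_keep > 0) sample(prev_bucks, n_keep),
              sample(setdiff(males, prev_bucks),
                     min(n_harem, length(setdiff(males, prev_bucks)))))
    if (length(pool) == 0L) pool <- males
    harem_of <- rep(seq_len(n_harem), each = cfg$does_per_buck)[seq_len(n_mat)]
    harem_buck <- sample(pool, n_harem, replace = length(pool) < n_harem)
    ## related matings: replace the buck by a paternal half-sib of the harem
    rel <- stats::runif(n_harem) < cfg$related_mating
    if (any(rel)) {
      for (h in which(rel)) {
        doe1 <- dams_g[match(h, harem_of)]
        fam1 <- sire_of[match(doe1, ids)]
        if (is.na(fam1)) next
        sibs <- ids[sex == "M" & !is.na(sire_of) & sire_of == fam1]
        if (length(sibs)) harem_buck[h] <- sibs[sample.int(length(sibs), 1)]
      }
    }
    kid_ids <- paste0("G", g, "_", seq_len(n_mat) + counter)
    counter <- counter + n_mat
    kid_sex <- sample(c("M", "F"), n_mat, replace = TRUE)
    kid_sire <- harem_buck[harem_of]
    ids <- c(ids, kid_ids)
    sex <- c(sex, kid_sex)
    gen <- c(gen, rep(g, n_mat))
    sire <- c(sire, kid_sire)
    dam <- c(dam, dams_g)
    sire_of <- c(sire_of, kid_sire)
    prev_bucks <- unique(harem_buck)
  }
  ped <- pedigree(ids, ifelse(is.na(sire), "0", sire),
                  ifelse(is.na(dam), "0", dam))
  ord <- match(ped$animal, ids)
  attr(ped, "sex") <- sex[ord]
  attr(ped, "generation") <- gen[ord]
  ped
}

#' Simulate breeding values over a pedigree
#'
#' Founders are drawn from `N(0, G0)`; non-founders as
#' `0.5 (a_sire + a_dam) + m` with Mendelian term
#' `m ~ N(0, d G0)`, `d = 0.5 - 0.25 (F_s + F_d)` (unknown parents
#' contribute 0 with compensating `d`).
#'
#' @param ped a [pedigree()] object.
#' @param G0 genetic covariance matrix (PSD).
#' @return matrix of breeding values, animals by traits, in pedigree order.
#' @export
simulate_breeding_values <- function(ped, G0) {
  stopifnot(inherits(ped, "cg_pedigree"))
  .check_psd(G0, "G0")
  k <- nrow(G0)
  n <- length(ped$animal)
  ## symmetric square root (chol fails on singular G0, e.g. the zero matrix)
  eg <- eigen(G0, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  z <- matrix(stats::rnorm(n * k), n, k) %*% rt
  a <- matrix(0, n, k, dimnames = list(ped$animal, NULL))
  s <- ped$sire_idx; d <- ped$dam_idx
  fs <- ifelse(is.na(s), 0, ped$f[s])
  fd <- ifelse(is.na(d), 0, ped$f[d])
  dvar <- ifelse(!is.na(s) & !is.na(d), 0.5 - 0.25 * (fs + fd),
                 ifelse(is.na(s) & is.na(d), 1, 0.75 - 0.25 * (fs + fd)))
  for (i in seq_len(n)) {
    pa <- numeric(k)
    if (!is.na(s[i])) pa <- pa + 0.5 * a[s[i], ]
    if (!is.na(d[i])) pa <- pa + 0.5 * a[d[i], ]
    a[i, ] <- pa + sqrt(dvar[i]) * z[i, ]
  }
  a
}

#' Calibrate a liability threshold to a target incidence
#'
#' Solves `mean(pnorm((mu - t) / sigma)) = target` for `t` by monotone
#' bisection to 1e-6, where `mu` are the record-level fixed-effect sums.
#'
#' @param target target incidence in (0, 1).
#' @param fixed_values numeric vector of fixed-effect sums over records.
#' @param total_var total (genetic + residual) liability variance.
#' @return the threshold `t`.
#' @export
calibrate_threshold <- function(target, fixed_values, total_var = 1) {
  stopifnot(target > 0, target < 1, total_var > 0)
  sig <- sqrt(total_var)
  fn <- function(t) mean(stats::pnorm((fixed_values - t) / sig)) - target
  lo <- min(fixed_values) - 10 * sig
  hi <- max(fixed_values) + 10 * sig
  while (hi - lo > 1e-6) {
    mid <- (lo + hi) / 2
    if (fn(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Simulate parity-wise binary abortion records
#'
#' Assigns fixed-effect levels, draws per-doe residual trait-vectors from
#' `R0` (so residuals are correlated across a doe's parities), forms
#' liabilities `fixed + a + e`, calibrates per-trait thresholds so the
#' expected incidence matches `cfg$incidence`, and thins later parities by
#' the cumulative retention probabilities.  Outcome 1 = abortion.
#'
#' @param ped a [pedigree()] from [simulate_pedigree()].
#' @param breeding_values animal-by-trait matrix from
#'   [simulate_breeding_values()].
#' @param cfg a [sim_config()].
#' @return a `cg_sim_dataset` list: `pedigree`, `records` (data.frame with
#'   doe_id, parity, outcome, year, season, age_class), `liabilities`,
#'   `breeding_values`, and `truth` (generating parameters + thresholds).
#' @export
simulate_records <- function(ped, breeding_values, cfg) {
  stopifnot(inherits(ped, "cg_pedigree"), inherits(cfg, "cg_sim_config"))
  k <- nrow(cfg$G0)
  sex <- attr(ped, "sex")
  gen <- attr(ped, "generation")
  cand <- which(sex == "F" & gen >= max(1L, cfg$n_generations - 1L))
  if (length(cand) < cfg$n_recorded_does) {
    cand <- which(sex == "F" & gen >= 1L)
  }
  n_doe <- min(cfg$n_recorded_does, length(cand))
  does <- sort(sample(cand, n_doe))

  n_year <- length(cfg$year_effects)
  ## a doe's first parity falls in a random year; later parities advance by
  ## one year, capped at the final recorded year
  year1 <- sample.int(n_year, n_doe, replace = TRUE)
  season <- matrix(sample.int(2L, n_doe * k, replace = TRUE), n_doe, k)
  age1 <- sample(1:2, n_doe, replace = TRUE, prob = c(0.7, 0.3))

  eg <- eigen(cfg$R0, symmetric = TRUE)
  rt <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  e <- matrix(stats::rnorm(n_doe * k), n_doe, k) %*% rt

  year <- season_lvl <- age <- fixed <- liab <- out <- matrix(NA_real_, n_doe, k)
  thresholds <- numeric(k)
  total_var <- diag(cfg$G0) + diag(cfg$R0)
  for (t in seq_len(k)) {
    yr <- pmin(year1 + (t - 1L), n_year)
    ag <- pmin(age1 + (t - 1L), length(cfg$age_effects))
    fx <- cfg$year_effects[yr] + cfg$season_effects[season[, t]] +
      cfg$age_effects[ag]
    thresholds[t] <- calibrate_threshold(cfg$incidence[t], fx, total_var[t])
    l <- fx + breeding_values[does, t] + e[, t]
    year[, t] <- yr
    season_lvl[, t] <- season[, t]
    age[, t] <- ag
    fixed[, t] <- fx
    liab[, t] <- l
    out[, t] <- as.numeric(l > thresholds[t])
  }

  ## nested retention: one uniform per doe against the cumulative curve
  u <- stats::runif(n_doe)
  keep <- outer(u, cfg$retention, "<=")

  rec <- do.call(rbind, lapply(seq_len(k), function(t) {
    idx <- which(keep[, t])
    data.frame(doe_id = ped$animal[does[idx]],
               parity = t,
               outcome = out[idx, t],
               year = 2016L + year[idx, t],
               season = c("first", "second")[season_lvl[idx, t]],
               age_class = paste0(age[idx, t], "yr"),
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  structure(list(
    pedigree = ped,
    records = rec,
    liabilities = liab,
    breeding_values = breeding_values,
    does = ped$animal[does],
    truth = list(G0 = cfg$G0, R0 = cfg$R0, thresholds = thresholds,
                 h2 = diag(cfg$G0) / (diag(cfg$G0) + diag(cfg$R0)),
                 year_effects = cfg$year_effects,
                 season_effects = cfg$season_effects,
                 age_effects = cfg$age_effects,
                 incidence = cfg$incidence)
  ), class = "cg_sim_dataset")
}

#' Simulate a complete synthetic dataset
#'
#' Convenience wrapper: seeds the RNG from `cfg$seed`, then runs
#' [simulate_pedigree()], [simulate_breeding_values()] and
#' [simulate_records()].
#'
#' @param cfg a [sim_config()].
#' @return a `cg_sim_dataset`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "cg_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  bv <- simulate_breeding_values(ped, cfg$G0)
  simulate_records(ped, bv, cfg)
}

#' @export
print.cg_sim_dataset <- function(x, ...) {
  counts <- table(x$records$parity)
  inc <- tapply(x$records$outcome, x$records$parity, mean)
  cat("<cg_sim_dataset> ", length(x$pedigree$animal), " pedigree animals, ",
      length(x$does), " recorded does\n", sep = "")
  for (t in names(counts)) {
    cat(sprintf("  parity %s: %d records, incidence %.3f\n",
                t, counts[[t]], inc[[t]]))
  }
  invisible(x)
}

#' Write phenotype records to CSV
#'
#' @param records the record data.frame of a `cg_sim_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read phenotype records from CSV
#'
#' @param path file written by [write_phenotypes()].
#' @return data.frame with doe_id, parity, outcome, year, season, age_class.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(doe_id = "character"))
  needed <- c("doe_id", "parity", "outcome", "year", "season", "age_class")
  if (!all(needed %in% names(df))) {
    stop("phenotype file must have columns: ", paste(needed, collapse = ", "))
  }
  df
}

#' Write generating truth parameters as YAML
#'
#' @param truth the `truth` element of a `cg_sim_dataset`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  tr <- truth
  tr$G0 <- as.vector(tr$G0)
  tr$R0 <- as.vector(tr$R0)
  yaml::write_yaml(tr, path)
  invisible(path)
}
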