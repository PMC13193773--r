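#' Build a validated, topologically sorted pedigree
#'
#' Constructs a `cg_pedigree` object from animal/sire/dam triples.  Animals
#' appearing only as parents are inserted as founders, rows are reordered so
#' that parents always precede offspring, and inbreeding coefficients are
#' computed with the Meuwissen--Luo indirect method.  Unknown parents are
#' treated as unrelated, non-inbred founders.
#'
#' @param animal,sire,dam character (or coercible) identifier vectors of
#'   equal length; `sire`/`dam` entries equal to `unknown_code` (or `NA`)
#'   mark unknown parents.
#' @param unknown_code token marking an unknown parent (default `"0"`).
#' @return A `cg_pedigree`: a list with elements `animal`, `sire`, `dam`
#'   (character, in topological order), `sire_idx`, `dam_idx` (integer
#'   indices, `NA` for unknown), `f` (inbreeding coefficients) and
#'   `index` (named integer vector mapping identifier to row).
#' @examples
#' ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
#' inbreeding_coefficients(ped)
#' @export
pedigree <- function(animal, sire, dam, unknown_code = "0") {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  stopifnot(length(animal) == length(sire), length(animal) == length(dam))
  sire[is.na(sire) | sire == unknown_code] <- NA_character_
  dam[is.na(dam) | dam == unknown_code] <- NA_character_

  if (anyDuplicated(animal)) {
    stop("duplicate animal id(s): ",
         paste(unique(animal[duplicated(animal)])[1:min(3, sum(duplicated(animal)))],
               collapse = ", "))
  }
  own <- which(animal == sire | animal == dam)
  if (length(own)) {
    stop("animal equal to its own parent: ", animal[own[1]])
  }

  ## implied founders: parents never listed as animals
  parents <- unique(c(sire, dam))
  parents <- parents[!is.na(parents)]
  implied <- setdiff(parents, animal)
  if (length(implied)) {
    animal <- c(animal, implied)
    sire <- c(sire, rep(NA_character_, length(implied)))
    dam <- c(dam, rep(NA_character_, length(implied)))
  }

  n <- length(animal)
  pos <- seq_len(n)
  names(pos) <- animal
  si <- unname(pos[sire])
  di <- unname(pos[dam])

  ## Kahn topological sort over parent links
  indeg <- integer(n)
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (!is.na(p)) {
        indeg[i] <- indeg[i] + 1L
        kids[[p]] <- c(kids[[p]], i)
      }
    }
  }
  order_out <- integer(n)
  queue <- integer(n)
  roots <- which(indeg == 0L)
  queue[seq_along(roots)] <- roots
  tail <- length(roots)
  head <- 1L
  filled <- 0L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    filled <- filled + 1L
    order_out[filled] <- v
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) {
        tail <- tail + 1L
        queue[tail] <- k
      }
    }
  }
  if (filled < n) {
    bad <- animal[which(indeg > 0L)[1]]
    stop("pedigree contains a cycle through animal: ", bad)
  }

  animal <- animal[order_out]
  newpos <- integer(n)
  newpos[order_out] <- seq_len(n)
  si <- newpos[si[order_out]]
  di <- newpos[di[order_out]]

  f <- .cg_inbreeding_ml(
    ifelse(is.na(si), -1L, si - 1L),
    ifelse(is.na(di), -1L, di - 1L)
  )

  index <- seq_len(n)
  names(index) <- animal
  structure(
    list(animal = animal,
         sire = ifelse(is.na(si), NA_character_, animal[si]),
         dam = ifelse(is.na(di), NA_character_, animal[di]),
         sire_idx = si, dam_idx = di, f = f, index = index),
    class = "cg_pedigree"
  )
}

#' Read a pedigree file
#'
#' Reads a delimited text file with at least three columns (animal, sire,
#' dam; extra columns ignored).  The delimiter is auto-detected from the
#' header line among comma, tab and semicolon unless given.
#'
#' @param path file path.
#' @param unknown_code token marking an unknown parent (default `"0"`).
#' @param sep field delimiter; `NULL` (default) auto-detects.
#' @return A [pedigree()] object.
#' @export
read_pedigree <- function(path, unknown_code = "0", sep = NULL) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  header <- readLines(path, n = 1L)
  if (is.null(sep)) {
    cand <- c(",", "\t", ";")
    hits <- vapply(cand, function(s) lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))), 1L)
    sep <- if (all(hits == 0L)) "," else cand[which.max(hits)]
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("pedigree file needs >= 3 columns (animal, sire, dam)")
  pedigree(df[[1]], df[[2]], df[[3]], unknown_code = unknown_code)
}

#' Inbreeding coefficients
#'
#' Per-animal inbreeding coefficients F (probability of identity by descent
#' of the two alleles at a locus), in pedigree order.
#'
#' @param ped a [pedigree()] object.
#' @return named numeric vector of F in `[0, 1)`.
#' @export
inbreeding_coefficients <- function(ped) {
  stopifnot(inherits(ped, "cg_pedigree"))
  stats::setNames(ped$f, ped$animal)
}

#' Additive (numerator) relationship matrix
#'
#' Builds the dense additive relationship matrix A by the tabular
#' (recursive) method: `A[i, j] = 0.5 * (A[s_i, j] + A[d_i, j])` for j
#' preceding i, and `A[i, i] = 1 + 0.5 * A[s_i, d_i]`.
#'
#' @param ped a [pedigree()] object.
#' @param max_animals guard for dense storage (default 5000); larger
#'   pedigrees should use [relationship_inverse()] directly.
#' @return dense symmetric matrix with `diag(A) = 1 + F`.
#' @export
relationship_matrix <- function(ped, max_animals = 5000L) {
  stopifnot(inherits(ped, "cg_pedigree"))
  n <- length(ped$animal)
  if (n > max_animals) {
    stop("pedigree has ", n, " animals, above the dense cap of ", max_animals,
         "; use relationship_inverse() for the sparse inverse")
  }
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  for (i in seq_len(n)) {
    s <- ped$sire_idx[i]; d <- ped$dam_idx[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + 0.5 * A[s, j]
      if (!is.na(d)) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the additive relationship matrix
#'
#' Assembles A-inverse animal-by-animal from Henderson's rules, using
#' Mendelian-sampling variances that account for parental inbreeding:
#' `d_i = 0.5 - 0.25 * (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 * F_p` with one, and 1 with none.
#'
#' @param ped a [pedigree()] object.
#' @return a symmetric sparse matrix (`Matrix::dsCMatrix`).
#' @export
relationship_inverse <- function(ped) {
  stopifnot(inherits(ped, "cg_pedigree"))
  n <- length(ped$animal)
  s <- ped$sire_idx; d <- ped$dam_idx
  fs <- ifelse(is.na(s), 0, ped$f[s])
  fd <- ifelse(is.na(d), 0, ped$f[d])
  both <- !is.na(s) & !is.na(d)
  one <- xor(is.na(s), is.na(d))
  dvar <- rep(1, n)
  dvar[both] <- 0.5 - 0.25 * (fs[both] + fd[both])
  dvar[one] <- 0.75 - 0.25 * (fs[one] + fd[one])  # the unknown one is 0
  w <- 1 / dvar

  ## vectorized triplet assembly (duplicate triplets are summed)
  idx <- seq_len(n)
  ii <- idx; jj <- idx; xx <- w                      # (i, i) += 1/d
  for (p in list(s, d)) {
    k <- !is.na(p)
    ii <- c(ii, idx[k]); jj <- c(jj, p[k]); xx <- c(xx, -0.5 * w[k])
    ii <- c(ii, p[k]); jj <- c(jj, idx[k]); xx <- c(xx, -0.5 * w[k])
    ii <- c(ii, p[k]); jj <- c(jj, p[k]); xx <- c(xx, 0.25 * w[k])
  }
  k <- both
  ii <- c(ii, s[k], d[k]); jj <- c(jj, d[k], s[k]); xx <- c(xx, rep(0.25 * w[k], 2))
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$animal, ped$animal))
  Matrix::forceSymmetric(Ainv)
}

#' Summarize pedigree structure
#'
#' Herd-book style structure counts and inbreeding statistics.  The mean
#' inbreeding coefficient is computed over inbred animals (F > 0) only.
#'
#' @param ped a [pedigree()] object.
#' @return a `cg_pedigree_summary` list of counts and proportions.
#' @export
summarize_pedigree <- function(ped) {
  stopifnot(inherits(ped, "cg_pedigree"))
  f <- ped$f
  both_known <- !is.na(ped$sire_idx) & !is.na(ped$dam_idx)
  both_unknown <- is.na(ped$sire_idx) & is.na(ped$dam_idx)
  inbred <- f > 0
  fpos <- f[inbred]
  structure(list(
    n_total = length(f),
    n_inbred = sum(inbred),
    n_sires = length(unique(ped$sire[!is.na(ped$sire)])),
    n_dams = length(unique(ped$dam[!is.na(ped$dam)])),
    n_both_known = sum(both_known),
    n_both_unknown = sum(both_unknown),
    n_one_unknown = sum(!both_known & !both_unknown),
    mean_f_inbred = if (length(fpos)) mean(fpos) else NA_real_,
    max_f = if (length(fpos)) max(fpos) else 0,
    min_f_positive = if (length(fpos)) min(fpos) else NA_real_
  ), class = "cg_pedigree_summary")
}

#' @export
print.cg_pedigree <- function(x, ...) {
  cat("<cg_pedigree> ", length(x$animal), " animals (",
      sum(is.na(x$sire_idx) & is.na(x$dam_idx)), " founders), ",
      sum(x$f > 0), " inbred\n", sep = "")
  invisible(x)
}

#' @export
print.cg_pedigree_summary <- function(x, ...) {
  lab <- c(n_total = "Individuals in total",
           n_inbred = "Inbreds in total",
           n_sires = "Sires in total",
           n_dams = "Dams in total",
           n_both_known = "Individuals with both parents known",
           n_both_unknown = "Individuals with both parents unknown",
           n_one_unknown = "Individuals with one parent unknown",
           mean_f_inbred = "Mean inbreeding in the inbreds",
           max_f = "Maximum inbreeding coefficient",
           min_f_positive = "Minimum positive inbreeding coefficient")
  for (k in names(lab)) {
    v <- x[[k]]
    cat(sprintf("%-42s %s\n", lab[[k]],
                if (is.numeric(v) && v %% 1 != 0) format(round(v, 4)) else format(v)))
  }
  invisible(x)
}

#' Write a pedigree summary as key-value text
#'
#' @param x a `cg_pedigree_summary`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pedigree_summary <- function(x, path) {
  stopifnot(inherits(x, "cg_pedigree_summary"))
  lines <- vapply(names(unclass(x)),
                  function(k) paste0(k, "\t", format(x[[k]], digits = 10)),
                  character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a pedigree to CSV
#'
#' @param ped a [pedigree()] object.
#' @param path output file.
#' @param unknown_code token written for unknown parents.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, unknown_code = "0") {
  stopifnot(inherits(ped, "cg_pedigree"))
  df <- data.frame(animal = ped$animal,
                   sire = ifelse(is.na(ped$sire), unknown_code, ped$sire),
                   dam = ifelse(is.na(ped$dam), unknown_code, ped$dam))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
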