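test_that("pedigree construction orders parents before offspring and inserts founders", {
  ped <- pedigree(c("C", "A", "B"), c("A", "0", "0"), c("B", "0", "0"))
  idx <- ped$index
  expect_true(idx[["C"]] > idx[["A"]] && idx[["C"]] > idx[["B"]])

  # implied founders: parents never listed as animals are added with F = 0
  ped2 <- pedigree("C", "A", "B")
  expect_length(ped2$animal, 3)
  expect_equal(unname(inbreeding_coefficients(ped2)), c(0, 0, 0))
})

test_that("structural errors are detected and named", {
  expect_error(pedigree(c("A", "B"), c("B", "A"), c("0", "0")), "cycle")
  expect_error(pedigree("A", "A", "0"), "own parent")
  expect_error(pedigree(c("A", "A"), c("0", "0"), c("0", "0")), "duplicate")
})

test_that("inbreeding matches classical closed forms", {
  # offspring of full sibs
  fs <- pedigree(c("A", "B", "C", "D", "E"),
                 c("0", "0", "A", "A", "C"), c("0", "0", "B", "B", "D"))
  expect_equal(unname(inbreeding_coefficients(fs)[["E"]]), 0.25)
  # offspring of parent-offspring mating
  po <- pedigree(c("A", "B", "C", "D"),
                 c("0", "0", "A", "A"), c("0", "0", "B", "C"))
  expect_equal(unname(inbreeding_coefficients(po)[["D"]]), 0.25)
  # offspring of half sibs
  hs <- pedigree(c("A", "B", "C", "D", "E", "X"),
                 c("0", "0", "0", "A", "A", "D"),
                 c("0", "0", "0", "B", "C", "E"))
  expect_equal(unname(inbreeding_coefficients(hs)[["X"]]), 0.125)
})

test_that("relationship matrix matches hand results on the trio", {
  ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  A <- relationship_matrix(ped)
  expect_equal(unname(A["C", "C"]), 1)
  expect_equal(unname(A["A", "C"]), 0.5)
  expect_equal(unname(A["B", "C"]), 0.5)
  expect_equal(unname(A["A", "B"]), 0)
  # unrelated founders: identity
  f <- founder_pedigree(4)
  expect_equal(unname(relationship_matrix(f)), diag(4))
  expect_equal(unname(as.matrix(relationship_inverse(f))), diag(4))
})

test_that("trio A-inverse equals the textbook Henderson result", {
  ped <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  Ai <- as.matrix(relationship_inverse(ped))
  expect_equal(unname(Ai),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)
})

test_that("dense-size cap redirects to the sparse inverse", {
  ped <- founder_pedigree(30)
  expect_error(relationship_matrix(ped, max_animals = 10), "cap")
})

test_that("tabular A agrees with a Cholesky-based oracle on a random pedigree", {
  set.seed(41)
  ped <- random_pedigree(50)
  A <- relationship_matrix(ped)
  # independent oracle: A = L D L' with L from gene-flow recursions
  n <- length(ped$animal)
  L <- diag(n)
  for (i in seq_len(n)) {
    for (p in c(ped$sire_idx[i], ped$dam_idx[i])) {
      if (!is.na(p)) L[i, seq_len(i - 1)] <- L[i, seq_len(i - 1)] + 0.5 * L[p, seq_len(i - 1)]
    }
    L[i, i] <- 1
  }
  fs <- ifelse(is.na(ped$sire_idx), 0, ped$f[ped$sire_idx])
  fd <- ifelse(is.na(ped$dam_idx), 0, ped$f[ped$dam_idx])
  both <- !is.na(ped$sire_idx) & !is.na(ped$dam_idx)
  one <- xor(is.na(ped$sire_idx), is.na(ped$dam_idx))
  dvar <- rep(1, n)
  dvar[both] <- 0.5 - 0.25 * (fs + fd)[both]
  dvar[one] <- 0.75 - 0.25 * (fs + fd)[one]
  A_oracle <- L %*% (dvar * t(L))
  expect_lt(max(abs(A - A_oracle)), 1e-10)
})

test_that("pedigree algebra invariants hold over random inbred pedigrees", {
  set.seed(99)
  for (rep in 1:12) {
    n <- sample(40:200, 1)
    ped <- random_pedigree(n)
    A <- relationship_matrix(ped)
    # two independent algorithms agree on the diagonal
    expect_equal(unname(diag(A) - 1), unname(ped$f), tolerance = 1e-12)
    # Henderson inverse really inverts the tabular matrix
    dev <- max(abs(as.matrix(relationship_inverse(ped) %*% A) - diag(n)))
    expect_lt(dev, 1e-8)
    # A is positive semi-definite
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values), -1e-9)
  }
})

test_that("outputs are invariant to input row order", {
  set.seed(7)
  df <- random_pedigree_frame(80, scramble = FALSE)
  ped1 <- pedigree(df$animal, df$sire, df$dam)
  perm <- sample.int(nrow(df))
  ped2 <- pedigree(df$animal[perm], df$sire[perm], df$dam[perm])
  f1 <- inbreeding_coefficients(ped1)
  f2 <- inbreeding_coefficients(ped2)
  expect_equal(f1[sort(names(f1))], f2[sort(names(f2))])
  A1 <- relationship_matrix(ped1)
  A2 <- relationship_matrix(ped2)
  ord <- ped1$animal
  expect_equal(A1[ord, ord], A2[ord, ord])
})

test_that("pedigree summary matches a brute-force recount", {
  set.seed(3)
  ped <- random_pedigree(1000)
  s <- summarize_pedigree(ped)
  expect_equal(s$n_total, 1000)
  expect_equal(s$n_both_known + s$n_both_unknown + s$n_one_unknown, s$n_total)
  # direct recount
  expect_equal(s$n_both_known, sum(!is.na(ped$sire) & !is.na(ped$dam)))
  expect_equal(s$n_both_unknown, sum(is.na(ped$sire) & is.na(ped$dam)))
  expect_equal(s$n_inbred, sum(ped$f > 0))
  expect_equal(s$n_sires, length(unique(stats::na.omit(ped$sire))))
  expect_equal(s$n_dams, length(unique(stats::na.omit(ped$dam))))
  expect_equal(s$mean_f_inbred, mean(ped$f[ped$f > 0]))
  expect_lte(s$mean_f_inbred, s$max_f)

  # trio: both-parent bookkeeping and a full-sib-mating herd of 5
  trio <- pedigree(c("A", "B", "C"), c("0", "0", "A"), c("0", "0", "B"))
  st <- summarize_pedigree(trio)
  expect_equal(st$n_both_known, 1)
  expect_equal(st$n_both_unknown, 2)
  expect_equal(st$n_inbred, 0)
  fs <- pedigree(c("A", "B", "C", "D", "E"),
                 c("0", "0", "A", "A", "C"), c("0", "0", "B", "B", "D"))
  sf <- summarize_pedigree(fs)
  expect_equal(sf$n_inbred, 1)
  expect_equal(sf$mean_f_inbred, 0.25)
})

test_that("pedigree files round-trip, with delimiter auto-detection", {
  set.seed(11)
  ped <- random_pedigree(60)
  csv <- tempfile(fileext = ".csv")
  write_pedigree(ped, csv)
  back <- read_pedigree(csv)
  expect_equal(back$animal, ped$animal)
  expect_equal(back$f, ped$f)
  # tab-separated variant
  tsv <- tempfile(fileext = ".tsv")
  df <- data.frame(animal = ped$animal,
                   sire = ifelse(is.na(ped$sire), "0", ped$sire),
                   dam = ifelse(is.na(ped$dam), "0", ped$dam))
  utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  back2 <- read_pedigree(tsv)
  expect_equal(back2$f, ped$f)
  expect_error(read_pedigree(tempfile()), "not found")
})
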