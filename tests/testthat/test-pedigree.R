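test_that("pedigree loading validates structure and orders parents first", {
  txt <- c("# comment line",
           "F1 dad 0 0 1",
           "F1 mom 0 0 2",
           "F1 kid dad mom 1")
  ped <- read_pedigree(textConnection(txt))
  expect_s3_class(ped, "pedigree")
  expect_equal(sum(ped$founder), 2L)
  expect_equal(length(ped$nonfounders), 1L)
  expect_equal(n_meioses(ped), 2L)

  # child listed before its parents in the file still topo-sorts
  ped2 <- read_pedigree(textConnection(c("F1 kid dad mom 1",
                                         "F1 dad 0 0 1",
                                         "F1 mom 0 0 2")))
  ki <- match("kid", ped2$id)
  expect_true(all(c(ped2$father[ki], ped2$mother[ki]) < ki))

  tg <- threegen_ped()
  expect_equal(sum(tg$founder), 4L)
  expect_equal(length(tg$nonfounders), 4L)
  for (i in tg$nonfounders)
    expect_true(tg$father[i] < i && tg$mother[i] < i)
})

test_that("each validation failure raises its own named condition", {
  expect_error(pedigree("a", "a", "a", 1), class = "gdtest_cycle")
  expect_error(pedigree(c("a", "b"), c("0", "a"), c("0", "0"), c(1, 2)),
               class = "gdtest_single_parent")
  expect_error(pedigree(c("a", "a"), c("0", "0"), c("0", "0"), c(1, 1)),
               class = "gdtest_duplicate_id")
  expect_error(pedigree("k", "x", "y", 1), class = "gdtest_unknown_parent")
  # two-node parent cycle
  expect_error(pedigree(c("a", "b", "c", "d"),
                        c("b", "a", "0", "0"), c("c", "c", "0", "0"),
                        c(1, 1, 2, 2)),
               class = "gdtest_cycle")
  # father recorded as female
  expect_error(pedigree(c("dad", "mom", "kid"), c("0", "0", "dad"),
                        c("0", "0", "mom"), c(2, 2, 1)),
               class = "gdtest_parent_sex")
  # same individual as father and mother
  expect_error(pedigree(c("p", "kid"), c("0", "p"), c("0", "p"), c(1, 1)),
               class = "gdtest_parent_sex")
})

test_that("kinship coefficients match classical values and the enumeration oracle", {
  expect_equal(kinship_matrix(trio_ped())["dad", "kid"], 0.25)
  expect_equal(kinship_matrix(trio_ped())["dad", "dad"], 0.5)
  expect_equal(kinship_matrix(nuclear_ped())["kid1", "kid2"], 0.25)
  expect_equal(kinship_matrix(halfsib_ped())["k1", "k2"], 0.125)
  expect_equal(kinship_matrix(cousin_ped())["c1", "c2"], 0.0625)
  expect_equal(kinship_matrix(inbred_ped())["c", "c"], 0.625)

  for (ped in list(trio_ped(), nuclear_ped(), halfsib_ped(),
                   cousin_ped(), inbred_ped())) {
    expect_equal(kinship_matrix(ped), kinship_by_enumeration(ped),
                 tolerance = 1e-12)
  }
})

test_that("inheritance-vector enumeration is exhaustive and capped", {
  expect_equal(nrow(enumerate_inheritance_vectors(trio_ped())), 4L)
  S <- enumerate_inheritance_vectors(nuclear_ped())
  expect_equal(nrow(S), 16L)
  expect_equal(nrow(unique(S)), 16L)
  expect_error(enumerate_inheritance_vectors(threegen_ped(), max_bits = 6L),
               "cap")
})

test_that("mean of the IBD matrix over all inheritance vectors is 4 * kinship", {
  for (ped in list(trio_ped(), nuclear_ped(), threegen_ped())) {
    S <- enumerate_inheritance_vectors(ped)
    acc <- 0
    for (k in seq_len(nrow(S))) acc <- acc + ibd_matrix(ped, S[k, ])
    expect_equal(acc / nrow(S), 4 * kinship_matrix(ped), tolerance = 1e-12)
  }
})

test_that("IBD counts behave as identity-by-descent theory requires", {
  trio <- trio_ped()
  S <- enumerate_inheritance_vectors(trio)
  for (k in seq_len(nrow(S))) {
    phi <- ibd_matrix(trio, S[k, ])
    expect_equal(phi["dad", "kid"], 1L)   # parent-child always share one
    expect_equal(phi["mom", "kid"], 1L)
    expect_equal(diag(phi), c(dad = 2L, mom = 2L, kid = 2L))
    expect_equal(phi["dad", "mom"], 0L)
  }
  # sibs copying identical grandparental alleles in both meioses: IBD 2
  nuc <- nuclear_ped()
  phi <- ibd_matrix(nuc, c(0L, 0L, 0L, 0L))
  expect_equal(phi["kid1", "kid2"], 2L)
  # opposite grandparental alleles in both meioses: IBD 0
  phi0 <- ibd_matrix(nuc, c(0L, 0L, 1L, 1L))
  expect_equal(phi0["kid1", "kid2"], 0L)
})

test_that("IBD is invariant to relabeling founder alleles", {
  ped <- threegen_ped()
  set.seed(3)
  for (k in 1:5) {
    s <- sample_inheritance_vector(ped)
    lab <- allele_labels(ped, s)
    perm <- sample(8L)              # permute the 2*4 founder labels
    lab2 <- matrix(perm[lab], ncol = 2L)
    phi2 <- outer(lab2[, 1], lab2[, 1], "==") +
      outer(lab2[, 1], lab2[, 2], "==") +
      outer(lab2[, 2], lab2[, 1], "==") +
      outer(lab2[, 2], lab2[, 2], "==")
    expect_equal(unname(ibd_matrix(ped, s)), unname(phi2 + 0L),
                 ignore_attr = TRUE)
  }
})

test_that("kinship and IBD are zero across families", {
  rows <- rbind(
    data.frame(fid = "A", id = c("d1", "m1", "k1"),
               father = c("0", "0", "d1"), mother = c("0", "0", "m1"),
               sex = c(1, 2, 1)),
    data.frame(fid = "B", id = c("d2", "m2", "k2"),
               father = c("0", "0", "d2"), mother = c("0", "0", "m2"),
               sex = c(1, 2, 2)))
  ped <- pedigree(rows$id, rows$father, rows$mother, rows$sex, rows$fid)
  psi <- kinship_matrix(ped)
  a <- ped$id[ped$fid == "A"]; b <- ped$id[ped$fid == "B"]
  expect_true(all(psi[a, b] == 0))
  set.seed(4)
  phi <- ibd_matrix(ped, sample_inheritance_vector(ped))
  expect_true(all(phi[a, b] == 0L))
})

test_that("sampled inheritance vectors have fair independent bits", {
  trio <- trio_ped()
  expect_length(sample_inheritance_vector(trio), 2L)
  expect_length(sample_inheritance_vector(threegen_ped()), 8L)
  set.seed(11)
  bits <- replicate(10000, sample_inheritance_vector(trio))
  means <- rowMeans(bits)
  expect_true(all(means > 0.47 & means < 0.53))
})
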