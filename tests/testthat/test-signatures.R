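test_that("signature scores are per-sample means of member-gene log2 values", {
  x <- matrix(c(2, 4, 6, 1, 3, 5), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  one <- score_signatures(x, list(signature_definition("solo", "g2")))
  expect_equal(unname(one["solo", ]), unname(x["g2", ]))

  trio <- score_signatures(x, list(signature_definition("trio", c("g1", "g2", "g3"))))
  expect_equal(unname(trio["trio", "s1"]), 4)

  set.seed(53)
  m <- matrix(rnorm(40 * 6, 8), 40, 6,
              dimnames = list(sprintf("g%02d", 1:40), sprintf("s%d", 1:6)))
  members <- sample(rownames(m), 20)
  sc <- score_signatures(m, list(signature_definition("rand", members)))
  for (s in colnames(m)) {
    expect_identical(sc["rand", s], mean(m[members, s]))
  }

  # affine equivariance: adding c to every member gene adds c to the score
  m2 <- m
  m2[members, ] <- m2[members, ] + 1.7
  sc2 <- score_signatures(m2, list(signature_definition("rand", members)))
  expect_equal(unname(sc2["rand", ]), unname(sc["rand", ] + 1.7), tolerance = 1e-12)

  expect_error(score_signatures(m, list(signature_definition("ghost", "NOPE"))),
               "ghost")
})

make_assoc_fixture <- function(n = 80, beta_score = 1, seed = 59) {
  set.seed(seed)
  score <- rnorm(n)
  age <- round(runif(n, 35, 80))
  gender <- sample(c("male", "female"), n, TRUE)
  p <- plogis(-0.2 + beta_score * score)
  y <- runif(n) < p
  meta <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     patient_id = sprintf("p%03d", 1:n),
                     primary_cancer = ifelse(y, "lung", "breast"),
                     tissue = "BM", age = age, gender = gender,
                     prior_treatment = FALSE, paired = FALSE,
                     stringsAsFactors = FALSE)
  scores <- matrix(score, 1, n, dimnames = list("sig", meta$sample_id))
  list(scores = scores, meta = meta)
}

test_that("logistic association recovers effects and honors its invariances", {
  fx <- make_assoc_fixture(n = 400, beta_score = 1, seed = 61)
  res <- associate_signatures(fx$scores, fx$meta)
  expect_true(res$converged)
  expect_lt(abs(res$coef - 1), 0.35)
  expect_lt(res$p_value, 1e-6)
  ref <- stats::glm(I(fx$meta$primary_cancer == "lung") ~ fx$scores[1, ] +
                      fx$meta$age + I(fx$meta$gender == "male"),
                    family = stats::binomial())
  expect_equal(res$coef, unname(stats::coef(ref)[2]), tolerance = 1e-8)

  # relabeling gender levels leaves the score term untouched
  flip <- fx$meta
  flip$gender <- ifelse(flip$gender == "male", "female", "male")
  res_flip <- associate_signatures(fx$scores, flip)
  expect_equal(res_flip$coef, res$coef, tolerance = 1e-6)
  expect_equal(res_flip$p_value, res$p_value, tolerance = 1e-6)

  # affine rescaling of age leaves the score p-value unchanged
  resc <- fx$meta
  resc$age <- resc$age / 10 + 3
  res_resc <- associate_signatures(fx$scores, resc)
  expect_equal(res_resc$p_value, res$p_value, tolerance = 1e-6)
})

test_that("constant scores give an uninformative fit, separation is flagged, Firth stays finite", {
  fx <- make_assoc_fixture(n = 60, beta_score = 0.5, seed = 67)
  const <- fx$scores; const[1, ] <- 2.5
  res_c <- associate_signatures(const, fx$meta)
  expect_equal(res_c$coef, 0)
  expect_equal(res_c$p_value, 1)

  # perfectly separating score
  sep <- fx$scores
  sep[1, ] <- ifelse(fx$meta$primary_cancer == "lung", 5, -5)
  res_s <- associate_signatures(sep, fx$meta)
  expect_false(res_s$converged)
  expect_true(is.na(res_s$p_value))
  expect_match(res_s$separation, "higher score predicts case")

  res_f <- associate_signatures(sep, fx$meta, firth = TRUE)
  expect_true(res_f$converged)
  expect_true(is.finite(res_f$coef) && is.finite(res_f$se))
  expect_gt(res_f$coef, 0)
})

test_that("PCA embedding matches the spectral oracle and fixes signs", {
  # two well-separated clusters: PC1 splits them and dominates the variance
  set.seed(71)
  n_g <- 16
  cl <- matrix(rnorm(n_g * 10, 0, 0.3), n_g, 10)
  cl[, 6:10] <- cl[, 6:10] + 4
  rownames(cl) <- sprintf("g%02d", 1:n_g)
  colnames(cl) <- sprintf("s%d", 1:10)
  emb <- pca_embedding(cl)
  expect_gt(emb$var_explained[1], 0.5)
  expect_true(all(emb$coords$PC1[1:5] < emb$coords$PC1[6:10]) ||
                all(emb$coords$PC1[1:5] > emb$coords$PC1[6:10]))

  # duplicated sample gets identical coordinates
  dup <- cbind(cl, s11 = cl[, 1])
  emb_d <- pca_embedding(dup)
  expect_equal(unlist(emb_d$coords[11, -1]), unlist(emb_d$coords[1, -1]),
               tolerance = 1e-10)

  # coordinates match an independent eigendecomposition of the covariance
  set.seed(73)
  m <- matrix(rnorm(32 * 25, 8), 32, 25,
              dimnames = list(sprintf("g%02d", 1:32), sprintf("s%02d", 1:25)))
  emb_m <- pca_embedding(m, n_comp = 2)
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  eig <- eigen(stats::cov(centered), symmetric = TRUE)
  for (j in 1:2) {
    ref <- centered %*% eig$vectors[, j]
    got <- emb_m$coords[[paste0("PC", j)]]
    expect_true(max(abs(got - ref)) < 1e-8 || max(abs(got + ref)) < 1e-8)
    expect_equal(emb_m$var_explained[j],
                 eig$values[j] / sum(eig$values), tolerance = 1e-10)
  }

  # invariant (up to nothing at all) to gene reordering
  perm <- sample(nrow(m))
  emb_p <- pca_embedding(m[perm, ], n_comp = 2)
  expect_equal(emb_p$coords$PC1, emb_m$coords$PC1, tolerance = 1e-8)

  # degenerate input: identical profiles
  flat <- matrix(5, 4, 5, dimnames = list(letters[1:4], LETTERS[1:5]))
  expect_error(pca_embedding(flat), "rank-deficient")
  expect_error(pca_embedding(m[, 1:2]), "3 samples")
})
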