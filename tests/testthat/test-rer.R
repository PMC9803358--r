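test_that("relative rates recover planted branch-length structure", {
  tr <- fixture_tree

  # exactly proportional element: zero residuals before normalization
  prop <- tr$phy
  prop$edge.length <- 3 * tr$phy$edge.length
  raw <- compute_rer(list(prop = prop), tr, normalize = FALSE)
  expect_lt(max(abs(raw), na.rm = TRUE), 1e-10)
  expect_equal(unname(attr(raw, "lambda")["prop"]), sqrt(3), tolerance = 1e-10)

  # a single doubled branch carries the element's largest residual
  one <- tr$phy
  one$edge.length[50] <- 2 * one$edge.length[50]
  r1 <- compute_rer(list(a = one), tr, normalize = FALSE)
  expect_equal(unname(which.max(r1[, 1])), 50L)

  # too few species: all-missing column
  few <- ape::keep.tip(tr$phy, tr$phy$tip.label[1:5])
  r2 <- compute_rer(list(few = few, prop = prop), tr, min_species = 10,
                    normalize = FALSE)
  expect_true(all(is.na(r2[, "few"])))
  expect_false(all(is.na(r2[, "prop"])))

  # a non-pruning is rejected
  alien <- ape::rtree(10)
  expect_error(compute_rer(list(x = alien), tr, min_species = 3),
               "not in master tree|not a valid pruning")
})

test_that("relative rates are invariant to element labels, order, and scale", {
  tr <- fixture_tree
  cfg <- simulation_config(n_elements = 40, fraction_responsive = 0,
                           delta = 0, sigma = 0.1, dropout_prob = 0.05,
                           seed = 8)
  sim <- simulate_elements(cfg, tr, fixture_hairless)
  R1 <- compute_rer(sim$elements, tr)

  shuffled <- sim$elements[sample(length(sim$elements))]
  names(shuffled) <- paste0("x_", names(shuffled))
  R2 <- compute_rer(shuffled, tr)
  expect_equal(unname(R2[, paste0("x_", colnames(R1))]), unname(R1),
               tolerance = 1e-12, ignore_attr = TRUE)

  # doubling one element's lengths changes its scale but not its branch ranking
  el <- sim$elements[[1]]
  el2 <- el
  el2$edge.length <- 2 * el$edge.length
  raw <- compute_rer(c(sim$elements, list(dbl = el2)), tr, normalize = FALSE)
  ok <- !is.na(raw[, 1]) & !is.na(raw[, "dbl"])
  expect_equal(rank(raw[ok, "dbl"]), rank(raw[ok, 1]))
})

test_that("null relative rates are standardized per branch", {
  tr <- fixture_tree
  cfg <- simulation_config(n_elements = 10000, fraction_responsive = 0,
                           delta = 0, sigma = 0.1, dropout_prob = 0, seed = 7)
  sim <- simulate_elements(cfg, tr, fixture_hairless)
  R <- compute_rer(sim$elements, tr)
  expect_lt(max(abs(rowMeans(R, na.rm = TRUE))), 0.05)
  sds <- apply(R, 1, sd, na.rm = TRUE)
  expect_true(all(abs(sds - 1) < 0.1))
})

test_that("covariate regression removes linear trait structure", {
  tr <- fixture_tree
  trait <- body_size_trait(tr, fixture_pheno)
  tv <- trait$branch_values

  # RER exactly affine in the trait: residuals vanish
  R <- matrix(rep(0.3 + 0.2 * tv, 3), ncol = 3,
              dimnames = list(names(tv), paste0("e", 1:3)))
  out <- regress_covariate(R, trait)
  expect_lt(max(abs(out)), 1e-10)

  # constant trait: residuals are the centered rates
  set.seed(2)
  R2 <- matrix(rnorm(121 * 2), 121, 2,
               dimnames = list(names(tv), c("a", "b")))
  const <- setNames(rep(1.7, 121), names(tv))
  out2 <- regress_covariate(R2, const)
  expect_equal(unname(out2), unname(scale(R2, scale = FALSE)),
               tolerance = 1e-10, ignore_attr = TRUE)

  # planted confounding: residuals orthogonal to the trait
  set.seed(3)
  R3 <- sapply(1:10, function(i) 0.5 * tv + rnorm(121, 0, 0.3))
  dimnames(R3) <- list(names(tv), paste0("c", 1:10))
  out3 <- regress_covariate(R3, trait)
  cors <- apply(out3, 2, cor, y = tv)
  expect_true(all(abs(cors) < 1e-8))

  # too few branches: unchanged with a warning
  R4 <- R2
  R4[, "a"] <- NA
  R4[1:2, "a"] <- c(1, 2)
  expect_warning(out4 <- regress_covariate(R4, trait), "passed through")
  expect_equal(out4[1:2, "a"], R4[1:2, "a"])

  # trait missing on a used branch: error
  tv_bad <- tv[-1]
  expect_error(regress_covariate(R2, tv_bad), "trait missing")
})

test_that("RER matrices survive a write/read round trip", {
  set.seed(4)
  R <- matrix(rnorm(12), 4, 3,
              dimnames = list(paste0("b", 1:4), paste0("e", 1:3)))
  R[2, 2] <- NA
  f <- tempfile(fileext = ".tsv")
  write_rer_matrix(R, f)
  expect_equal(read_rer_matrix(f), R, tolerance = 1e-12)
})
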