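test_that("ranking scores are signed negative log p-values", {
  res <- data.frame(element_id = c("a", "b", "c"),
                    statistic = c(0.4, -0.4, 0),
                    p = c(0.01, 0.01, 1))
  s <- rank_scores(res)
  expect_equal(unname(s), c(-log(0.01), log(0.01), 0), tolerance = 1e-9)
  expect_equal(unname(rank_scores(res, literal = TRUE)), -unname(s))

  # a parametric 0 falls back to the floored permulation p
  res0 <- data.frame(element_id = "a", statistic = 0.5, p = 0, permp = 0.001)
  expect_equal(unname(rank_scores(res0)), -log(0.001))
  res0$permp <- NULL
  expect_error(rank_scores(res0), "permp")
})

test_that("the AUC enrichment statistic attains its exact extremes", {
  # 20-member set occupying the top of a 200-element ranking
  scores <- setNames(seq_len(200), paste0("e", 1:200))
  top <- paste0("e", 181:200)
  enr <- wilcoxon_enrich(scores, list(top = top), min_set = 10)
  expect_equal(enr$statistic, 0.5)
  expect_lt(enr$p, 1e-10)
  # the reverse: bottom of the ranking
  bottom <- paste0("e", 1:20)
  expect_equal(wilcoxon_enrich(scores, list(b = bottom), min_set = 10)$statistic,
               -0.5)
  # balanced interleaving (member, background, background, member blocks)
  inter <- paste0("e", sort(c(seq(1, 200, by = 4), seq(4, 200, by = 4))))
  expect_equal(wilcoxon_enrich(scores, list(i = inter), min_set = 10)$statistic,
               0)
})

test_that("enrichment p-values match the exhaustive U distribution", {
  set.seed(60)
  for (rep in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    sc <- rnorm(n1 + n2)
    names(sc) <- paste0("e", seq_along(sc))
    members <- paste0("e", 1:n1)
    enr <- wilcoxon_enrich(sc, list(s = members), min_set = 2)
    expect_equal(enr$p, u_exact_p(sc[1:n1], sc[-(1:n1)]), tolerance = 1e-12)
    # statistic equals the independent pairwise-comparison AUC
    pairs <- outer(sc[1:n1], sc[-(1:n1)], ">")
    expect_equal(enr$statistic, mean(pairs) - 0.5, tolerance = 1e-12)
  }
})

test_that("enrichment is invariant to monotone score transforms", {
  set.seed(61)
  sc <- setNames(rnorm(80), paste0("e", 1:80))
  ann <- list(s1 = paste0("e", sample(80, 15)), s2 = paste0("e", sample(80, 12)))
  e1 <- wilcoxon_enrich(sc, ann, min_set = 10)
  e2 <- wilcoxon_enrich(exp(sc), ann, min_set = 10)
  e3 <- wilcoxon_enrich(3 * sc + 10, ann, min_set = 10)
  expect_equal(e1$statistic, e2$statistic)
  expect_equal(e1$p, e2$p)
  expect_equal(e1$statistic, e3$statistic)
})

test_that("proximity mapping honors the inclusive window boundary", {
  cnes <- data.frame(chrom = "chr1",
                     start = c(5000, 5000, 30000, 100000),
                     end = c(5100, 5100, 30100, 100100),
                     name = c("cne_at10k", "cne_at10k_dup", "cne_inside",
                              "cne_far"))
  cnes <- cnes[-2, ]
  genes <- data.frame(chrom = "chr1",
                      start = c(15100, 25000, 115101),
                      end = c(20000, 40000, 120000),
                      name = c("gene_gap10000", "gene_overlap", "gene_gap10001"))
  m <- map_by_proximity(cnes, genes, window = 10000)
  expect_true("cne_at10k" %in% m$gene_gap10000)      # gap exactly 10,000
  expect_true("cne_inside" %in% m$gene_overlap)      # contained, distance 0
  expect_false("cne_far" %in% unlist(m["gene_gap10001"]))  # gap 10,001
  expect_error(map_by_proximity(data.frame(chrom = "c", start = 5, end = 5,
                                           name = "bad"), genes),
               "malformed")
})

test_that("geneset permulation p-values flag planted sets and spare decoys", {
  tr <- fixture_tree
  cfg <- simulation_config(n_elements = 150, fraction_responsive = 0.2,
                           delta = 1, sigma = 0.1, dropout_prob = 0, seed = 62)
  sim <- simulate_elements(cfg, tr, fixture_hairless)
  ann <- make_fixture_annotations(sim$truth, n_decoy_sets = 6, seed = 63)
  R <- compute_rer(sim$elements, tr)
  a <- associate(R, fixture_hairless)
  nulls <- permulate_binary(tr, 10, 200, seed = 64)
  ap <- permulation_pvalues(R, a, nulls)
  scores <- rank_scores(ap)
  enr <- wilcoxon_enrich(scores, ann, min_set = 10)
  enr <- enrich_permp(attr(ap, "null_stats"), attr(ap, "null_p"), ann, enr,
                      scored_elements = names(scores))
  expect_equal(enr$permp[enr$set_name == "hair"], 1 / 200)
  expect_equal(enr$statistic[enr$set_name == "hair"],
               max(enr$statistic))
  expect_gt(min(enr$permp[enr$set_name != "hair"]), 1 / 200)
  # an incomplete cache is refused with the missing ids
  expect_error(
    enrich_permp(attr(ap, "null_stats")[-1, ], attr(ap, "null_p")[-1, ], ann,
                 enr, scored_elements = names(scores)),
    "incomplete")
})

test_that("planted enrichment is robust to dropping one foreground species", {
  tr <- fixture_tree
  cfg <- simulation_config(n_elements = 150, fraction_responsive = 0.2,
                           delta = 1, sigma = 0.1, dropout_prob = 0, seed = 65)
  sim <- simulate_elements(cfg, tr, fixture_hairless)
  ann <- make_fixture_annotations(sim$truth, n_decoy_sets = 6, seed = 66)
  R <- compute_rer(sim$elements, tr)
  hairless_tips <- intersect(fixture_hairless$branch_names,
                             tr$phy$tip.label)
  reduced <- hairless_foreground(
    tr, within(fixture_pheno, hairless[species == "susScr3"] <- 0))
  expect_length(reduced$branch_index, 10)
  a <- associate(R, reduced)
  enr <- wilcoxon_enrich(rank_scores(a), ann, min_set = 10)
  expect_equal(enr$statistic[enr$set_name == "hair"], max(enr$statistic))
  expect_lt(enr$p_adj[enr$set_name == "hair"], 0.05)
})

test_that("GMT files round-trip", {
  sets <- list(alpha = c("g1", "g2", "g3"), beta = c("g2", "g9"))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  back <- read_gmt(f)
  expect_equal(back[order(names(back))], sets[order(names(sets))])
})
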