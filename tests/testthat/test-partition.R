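# association results with every SNP "significant"; p ordered as given
fake_results <- function(snps, p, pos = NULL) {
  tibble::tibble(snp_id = snps, p = p,
                 pos = pos %||% seq_along(snps) * 1000L)
}

test_that("greedy clumping finds one index per planted independent cluster", {
  sim <- simulate_cluster_panel(3000, n_clusters = 3,
                                fillers_per_cluster = 2,
                                within_r2 = 0.98, seed = 51)
  ld <- suppressWarnings(ld_pairs(sim$geno))
  snps <- sim$geno$variants$snp_id
  withr::with_seed(52, res <- fake_results(snps, runif(length(snps), 1e-8, 1e-4)))
  idx <- select_index_snps(res, ld, p_threshold = 0.05,
                           r2_independence = 0.9)
  expect_length(idx, 3)
  truth <- setNames(sim$truth$clusters$cluster, sim$truth$clusters$snp_id)
  expect_setequal(unique(truth[idx]), c("idx1", "idx2", "idx3"))
})

test_that("clumping degenerates correctly at the threshold extremes", {
  sim <- simulate_cluster_panel(2000, n_clusters = 1,
                                fillers_per_cluster = 3,
                                within_r2 = 0.95, seed = 53)
  ld <- suppressWarnings(ld_pairs(sim$geno))
  snps <- sim$geno$variants$snp_id
  res <- fake_results(snps, c(1e-6, 1e-5, 1e-4, 1e-3))
  # one tight cluster: a single index, the smallest p
  idx <- select_index_snps(res, ld, r2_independence = 0.9)
  expect_equal(idx, "idx1")
  # independence bound 1: every significant SNP is its own index
  idx_all <- select_index_snps(res, ld, r2_independence = 1.0)
  expect_setequal(idx_all, snps)
  # nothing significant: empty with a warning
  res0 <- dplyr::mutate(res, p = 0.9)
  expect_warning(idx0 <- select_index_snps(res0, ld), "no SNP")
  expect_length(idx0, 0)
})

test_that("cluster assignment follows the argmax rule with stated tie-breaks", {
  ld <- tibble::tibble(snp_a = c("s", "s", "t", "t", "u", "u", "A"),
                       snp_b = c("A", "B", "A", "B", "A", "B", "B"),
                       r2 = c(0.95, 0.92, 0.5, 0.2, 0.88, 0.88, 0.1))
  pos <- c(A = 1000, B = 9000, s = 2000, t = 1500, u = 8000)
  ca <- assign_clusters(c("s", "t", "u", "A", "B"), c("A", "B"), ld,
                        r2_floor = 0.3, positions = pos)
  a <- setNames(ca$assignment$index, ca$assignment$snp_id)
  expect_equal(unname(a["s"]), "A")        # 0.95 beats 0.92
  expect_equal(unname(a["u"]), "B")        # exact tie: B is nearer
  expect_equal(unname(a["A"]), "A")        # indices map to themselves
  expect_equal(unname(a["B"]), "B")
  expect_equal(unname(a["t"]), "A")
  # below the floor: unassigned
  ca2 <- assign_clusters(c("t"), c("A", "B"),
                         dplyr::add_row(ld, snp_a = "t", snp_b = "B",
                                        r2 = 0.1),
                         r2_floor = 0.6, positions = pos)
  expect_equal(ca2$unassigned, "t")
  expect_equal(nrow(ca2$assignment), 0)
  # missing LD entry is an input error naming the pair
  expect_error(assign_clusters(c("z"), c("A", "B"), ld),
               class = "finemapld_input_error")
})

test_that("partitioning a dense planted panel reaches 95% accuracy", {
  sim <- simulate_cluster_panel(2000, n_clusters = 7,
                                fillers_per_cluster = 3,
                                within_r2 = 0.95, seed = 54)
  ld <- suppressWarnings(ld_pairs(sim$geno))
  truth <- setNames(sim$truth$clusters$cluster, sim$truth$clusters$snp_id)
  idx <- sprintf("idx%d", 1:7)
  ca <- assign_clusters(sim$geno$variants$snp_id, idx, ld,
                        positions = setNames(sim$geno$variants$pos,
                                             sim$geno$variants$snp_id))
  acc <- mean(ca$assignment$index == truth[ca$assignment$snp_id])
  expect_gte(acc, 0.95)
})

test_that("dropping clusters removes whole bins and keeps an audit trail", {
  ld <- tibble::tibble(snp_a = c("x", "x", "y", "y", "A"),
                       snp_b = c("A", "B", "A", "B", "B"),
                       r2 = c(0.95, 0.2, 0.1, 0.96, 0.05))
  ca <- assign_clusters(c("x", "y", "A", "B"), c("A", "B"), ld)
  red <- drop_clusters(ca, c(B = "marginal p = 0.412, direction rule"))
  expect_equal(red$index_snps, "A")
  expect_setequal(red$assignment$snp_id, c("x", "A"))
  expect_equal(red$dropped$index, "B")
  # empty evidence is the identity
  expect_equal(drop_clusters(ca, character(0)), ca)
  expect_error(drop_clusters(ca, c(Z = "no such cluster")),
               class = "finemapld_key_error")
})

test_that("identical panels make the intersection equal each group set", {
  sim <- simulate_cluster_panel(1500, n_clusters = 2,
                                fillers_per_cluster = 2,
                                within_r2 = 0.98, seed = 55)
  panels <- list(g1 = sim$geno, g2 = sim$geno, g3 = sim$geno)
  cs <- transethnic_filter("idx1", panels, 0.9)
  expect_setequal(cs$intersection, cs$per_group_sets$g1)
  expect_equal(cs$venn_counts$pattern, "g1&g2&g3")
})

test_that("trans-ethnic intersection recovers exactly the shared causal cluster", {
  sims <- lapply(1:3, function(i)
    simulate_cluster_panel(1500, n_clusters = 3, fillers_per_cluster = 2,
                           within_r2 = 0.98, private_fillers = 2,
                           population = paste0("G", i), seed = 55 + i))
  panels <- setNames(lapply(sims, `[[`, "geno"), paste0("G", 1:3))
  cs <- transethnic_filter("idx1", panels, 0.9)
  shared <- c("idx1", "idx1_f1", "idx1_f2")
  expect_setequal(cs$intersection, shared)
  # private proxies appear in exactly one group's set
  expect_true("idx1_G1_p1" %in% cs$per_group_sets$G1)
  expect_false("idx1_G1_p1" %in% cs$intersection)
  # venn counts cover the union
  expect_equal(sum(cs$venn_counts$count),
               length(unique(unlist(cs$per_group_sets))))
})

test_that("raising a group's threshold never enlarges its set or the intersection", {
  sim <- simulate_cluster_panel(1500, n_clusters = 1,
                                fillers_per_cluster = 4,
                                within_r2 = 0.9, seed = 59)
  panels <- list(g1 = sim$geno, g2 = sim$geno)
  lo <- transethnic_filter("idx1", panels, c(g1 = 0.5, g2 = 0.5))
  hi <- transethnic_filter("idx1", panels, c(g1 = 0.95, g2 = 0.5))
  expect_true(all(hi$per_group_sets$g1 %in% lo$per_group_sets$g1))
  expect_true(all(hi$intersection %in% lo$intersection))
  # group order does not change the venn counts
  rev_cs <- transethnic_filter("idx1", rev(panels), c(g1 = 0.5, g2 = 0.5))
  expect_setequal(lo$intersection, rev_cs$intersection)
  expect_equal(sum(lo$venn_counts$count), sum(rev_cs$venn_counts$count))
})

test_that("disjoint proxy sets give an empty intersection and no triple overlap", {
  withr::with_seed(60, {
    g1 <- make_gm(cbind(idxA = rbinom(300, 2, .3), pA = rbinom(300, 2, .3)))
    g2 <- make_gm(cbind(idxA = rbinom(300, 2, .3), pB = rbinom(300, 2, .3)))
  })
  # idxA polymorphic in both but its proxies are unrelated noise
  cs <- transethnic_filter("idxA", list(g1 = g1, g2 = g2), 0.99)
  expect_equal(cs$intersection, "idxA")  # the index always proxies itself
  expect_error(transethnic_filter("missing", list(g1 = g1), 0.9),
               class = "finemapld_input_error")
})
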