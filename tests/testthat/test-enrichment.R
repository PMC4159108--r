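toy_world <- function(n_mirna = 20, obs_k = 8) {
  ids <- sprintf("m%02d", seq_len(n_mirna))
  obs <- ids[seq_len(obs_k)]
  list(ids = ids, obs = obs)
}

test_that("evidence QC keeps r < -0.5 in >= 2 distinct datasets, strictly", {
  ev <- data.frame(
    mirna_id = c("m1", "m1", "m2", "m3", "m3", "m3", "m4", "m4"),
    gene_id = c("g1", "g1", "g2", "g3", "g3", "g3", "g4", "g4"),
    dataset_id = c("D1", "D2", "D1", "D1", "D2", "D3", "D1", "D1"),
    r = c(-0.6, -0.7, -0.6, -0.5, -0.5, -0.5, -0.8, -0.9),
    stringsAsFactors = FALSE)
  vm <- filter_evidence(ev)
  expect_equal(vm$target_map, list(m1 = "g1"))   # m2: 1 dataset; m3: r not < -0.5
  expect_equal(unname(vm$n_targets[c("m1", "m2", "m3", "m4")]), c(1L, 0L, 0L, 0L))
  # m4: strong r but a single distinct dataset (duplicated) -> dropped
  expect_equal(unname(vm$confidence["m1"]), "high")
  expect_equal(unname(vm$confidence["m4"]), "low")
  expect_equal(vm$pairs$n_datasets, 2L)
  expect_equal(vm$pairs$min_r, -0.7)
})

test_that("target bootstrap: saturated and empty genes get p_emp = 1", {
  w <- toy_world()
  tm <- lapply(setNames(w$ids, w$ids), function(m) "gAll")
  res <- bootstrap_target_enrichment(w$obs, w$ids, tm, B = 50, seed = 2)
  # every catalog miRNA targets gAll: any null 8-set scores 8 too
  expect_equal(res$observed[res$unit == "gAll"], 8L)
  expect_equal(res$p_emp[res$unit == "gAll"], 1)
  # a gene targeted only by a non-observed miRNA: observed 0, p 1
  tm3 <- list(m09 = "gOnlyNull")
  res3 <- bootstrap_target_enrichment(w$obs, w$ids, tm3, B = 50, seed = 2)
  expect_equal(res3$observed[res3$unit == "gOnlyNull"], 0L)
  expect_equal(res3$p_emp[res3$unit == "gOnlyNull"], 1)
})

test_that("target bootstrap matches the combinatorial oracle in the toy world", {
  w <- toy_world()
  tm <- lapply(setNames(w$obs, w$obs), function(m) "gObs")
  B <- 2000
  res <- bootstrap_target_enrichment(w$obs, w$ids, tm, B = B, seed = 42)
  # analytic: P(random 8-set == the observed 8) = 1/choose(20,8) ~ 7.9e-6,
  # so no null replicate should reach the observed count of 8
  expect_lt(B / choose(20, 8), 0.02)
  expect_equal(res$observed[res$unit == "gObs"], 8L)
  expect_equal(res$p_emp[res$unit == "gObs"], 1 / (B + 1))
  expect_true(res$enriched[res$unit == "gObs"])
})

test_that("bootstraps are deterministic under a fixed seed", {
  w <- toy_world()
  set.seed(7)
  tm <- lapply(setNames(w$ids, w$ids),
               function(m) sample(sprintf("g%02d", 1:30), 5))
  r1 <- bootstrap_target_enrichment(w$obs, w$ids, tm, B = 200, seed = 9)
  r2 <- bootstrap_target_enrichment(w$obs, w$ids, tm, B = 200, seed = 9)
  expect_identical(r1, r2)
  r3 <- bootstrap_target_enrichment(w$obs, w$ids, tm, B = 200, seed = 10)
  expect_false(identical(r1$null_exceed, r3$null_exceed))
  # argument validation
  expect_error(bootstrap_target_enrichment(w$obs, w$ids, tm, B = 0), "B must")
  expect_error(bootstrap_target_enrichment(c(w$obs, "mXX"), w$ids, tm, B = 10),
               "mXX")
})

test_that("raising a gene's observed count never raises its p_emp (same draws)", {
  w <- toy_world()
  set.seed(13)
  tm <- lapply(setNames(w$ids, w$ids),
               function(m) sample(sprintf("g%02d", 1:10), 3))
  g <- "g05"
  # ensure some observed miRNA does not yet target g, then add that edge
  free <- w$obs[!vapply(tm[w$obs], function(x) g %in% x, logical(1))]
  expect_gt(length(free), 0)
  tm2 <- tm
  tm2[[free[1]]] <- c(tm2[[free[1]]], g)
  r1 <- bootstrap_target_enrichment(w$obs, w$ids, tm, B = 500, seed = 3)
  r2 <- bootstrap_target_enrichment(w$obs, w$ids, tm2, B = 500, seed = 3)
  expect_equal(r2$observed[r2$unit == g], r1$observed[r1$unit == g] + 1L)
  expect_lte(r2$p_emp[r2$unit == g], r1$p_emp[r1$unit == g])
})

test_that("process bootstrap counts annotated target genes per process", {
  w <- toy_world()
  # each observed miRNA exclusively targets its own gene; process P1 annotates
  # all 8, so only the exact observed set ties the count of 8
  # (P(tie) = 1/choose(20,8) per replicate)
  tm <- list()
  for (i in 1:8) tm[[w$obs[i]]] <- sprintf("g%d", i)
  for (m in setdiff(w$ids, w$obs)) tm[[m]] <- "g9"
  go <- list(annotations = data.frame(
    gene_id = c(sprintf("g%d", 1:8), "g9", "g10"),
    process_id = c(rep("P1", 8), "P2", "P3"),
    stringsAsFactors = FALSE),
    background = c(sprintf("g%d", 1:8), "g9", "g10"))
  res <- bootstrap_process_enrichment(w$obs, w$ids, tm, go, B = 400, seed = 5)
  expect_equal(res$observed[res$unit == "P1"], 8L)
  expect_equal(res$p_emp[res$unit == "P1"], 1 / 401)
  # P3 annotates a gene nobody targets: observed 0, p 1
  expect_equal(res$observed[res$unit == "P3"], 0L)
  expect_equal(res$p_emp[res$unit == "P3"], 1)
  # presence/absence mode is a valid switch
  resb <- bootstrap_process_enrichment(w$obs, w$ids, tm, go, B = 100, seed = 5,
                                       statistic = "presence")
  expect_true(all(resb$observed %in% c(0L, 1L)))
  # a miRNA set with no validated targets observes 0 everywhere
  res0 <- bootstrap_process_enrichment(w$ids[9:10], w$ids,
                                       tm["m01"], go, B = 50, seed = 5)
  expect_true(all(res0$observed == 0L))
})

test_that("hypergeometric GO enrichment matches the exact tail sum", {
  bg <- sprintf("g%03d", 1:100)
  term_genes <- bg[1:10]
  go <- list(annotations = data.frame(gene_id = c(term_genes, bg),
                                      process_id = c(rep("T1", 10),
                                                     rep("ALL", 100))),
             background = bg)
  targets <- c(term_genes, bg[11:20])   # 20 targets containing all 10 of T1
  res <- genomic_go_enrichment(targets, go)
  # exact upper tail: P(X >= 10) with N=100, K=10, n=20
  p_exact <- sum(choose(10, 10) * choose(90, 10) / choose(100, 20))
  expect_equal(res$p[res$unit == "T1"], p_exact)
  # a term annotating the whole background is uninformative: p = 1
  expect_equal(res$p[res$unit == "ALL"], 1)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_error(genomic_go_enrichment(character(), go), "empty")
  expect_error(genomic_go_enrichment("not_a_gene", go), "outside")
})

test_that("disease bootstrap matches the binomial oracle", {
  ids <- sprintf("m%03d", 1:100)
  dd <- data.frame(mirna_id = ids[1:10], disease_name = "cancer",
                   direction = "up", stringsAsFactors = FALSE)
  pd <- ids[1:31]
  res <- disease_bootstrap(pd, dd, ids, B = 4000, seed = 8)
  expect_equal(res$observed_count, 10)
  # null mean: 31 draws at association rate 0.1 -> 3.1
  expect_equal(res$expectation, 3.1, tolerance = 0.1)
  expect_lt(res$p_emp, 0.01)
  expect_true(res$ci95[1] <= res$expectation &&
              res$expectation <= res$ci95[2])
  # every miRNA associated: expectation k, p_emp 1
  dd_all <- data.frame(mirna_id = ids, disease_name = "x", direction = "up")
  r2 <- disease_bootstrap(pd, dd_all, ids, B = 200, seed = 8)
  expect_equal(r2$expectation, 31)
  expect_equal(r2$p_emp, 1)
  # observed 0 -> p_emp 1
  dd_none <- dd[0, ]
  r3 <- disease_bootstrap(pd, dd_none, ids, B = 200, seed = 8)
  expect_equal(r3$observed_count, 0)
  expect_equal(r3$p_emp, 1)
  expect_error(disease_bootstrap(ids, dd, ids[1:5], B = 10, replace = FALSE),
               "larger than catalog")
})

test_that("planted enriched genes are recovered at p_emp < 0.05", {
  ids <- sprintf("m%03d", 1:100)
  planted <- ids[1:8]
  world <- simulate_enrichment_world(ids, n_genes = 120, planted_set = planted,
                                     effect = 1, n_planted_genes = 15,
                                     q = 0.05, pass_rate = 1, seed = 17)
  vm <- filter_evidence(world$evidence)
  res <- bootstrap_target_enrichment(planted, ids, vm$target_map, B = 400,
                                     seed = 17)
  hits <- res$enriched[res$unit %in% world$truth$planted_genes]
  expect_gte(mean(hits), 0.9)
})
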