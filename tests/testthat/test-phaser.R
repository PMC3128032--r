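# Per-CNV orchestration: k sweep, adjustment, conservation invariants, CLI.

test_that("max_clusters follows the totals range with cap and floor", {
  expect_equal(max_clusters(c(2, 3, 4)), 5L)
  expect_equal(max_clusters(c(2)), 3L)
  expect_equal(max_clusters(c(1), n_vertices = 2L), 2L)   # capped
  expect_equal(max_clusters(c(0, 0)), 2L)                 # floored at 2
  expect_error(max_clusters(NA_integer_), "non-missing")
})

test_that("a single shared background haplotype yields all-1/1 calls", {
  strings <- rep("01011010", 10)          # 5 individuals, one haplotype
  local <- local_from_strings(strings)
  cs <- infer_cnv(local, totals = rep(2L, 5), restarts = 10, seed = 3)
  expect_true(all(cs$calls$copy_hapA == 1L & cs$calls$copy_hapB == 1L))
  expect_true(all(cs$calls$satisfied))
})

test_that("an odd total forces two different copy numbers", {
  local <- local_from_strings(c("0000", "1111"))
  cs <- infer_cnv(local, totals = 3L, restarts = 10, seed = 5)
  expect_equal(cs$calls$copy_hapA + cs$calls$copy_hapB, 3L)
  expect_true(cs$calls$copy_hapA != cs$calls$copy_hapB)
  expect_true(cs$cluster_labels[1] != cs$cluster_labels[2])
})

test_that("conservation holds across simulated panels", {
  for (s in 1:3) {
    cfg <- sim_config(copy_freqs = c("0" = 0.2, "1" = 0.6, "2" = 0.2),
                      ld_flip_fraction = 0.25, seed = 100 + s)
    sim <- simulate_panel(cfg)
    cs <- run_sim_pipeline(sim, seed = 200 + s)
    ok <- cs$calls$copy_hapA >= 0
    # every resolved call sums to the individual's total
    expect_true(all((cs$calls$copy_hapA + cs$calls$copy_hapB)[ok] ==
                    cs$calls$total[ok]))
    # odd totals yield unequal pairs
    odd <- ok & cs$calls$total %% 2L == 1L
    expect_true(all(cs$calls$copy_hapA[odd] != cs$calls$copy_hapB[odd]))
    # all hard edges cut in the final clustering
    lab <- cs$cluster_labels
    for (i in which(cs$calls$total %% 2L == 1L)) {
      expect_true(lab[2 * i - 1] != lab[2 * i])
    }
  }
})

test_that("inference is deterministic under a fixed seed", {
  sim <- simulate_panel(sim_config(ld_flip_fraction = 0.3, seed = 77))
  a <- run_sim_pipeline(sim, seed = 9)
  b <- run_sim_pipeline(sim, seed = 9)
  expect_identical(a$calls, b$calls)
  expect_identical(a$chosen_k, b$chosen_k)
  expect_identical(a$cluster_labels, b$cluster_labels)
})

test_that("individuals with missing totals are excluded from one CNV only", {
  panel <- tiny_panel()
  cnv <- tiny_cnv(totals = c(s1 = 2L, s2 = NA))
  local <- select_window(panel, cnv, 1.0)
  cs <- infer_cnv(local, cnv, restarts = 5, seed = 1)
  expect_equal(cs$calls$sample_id, "s1")
})

test_that("adjustment is a fixpoint on satisfied input and honours forced pairs", {
  # already satisfied: both haplotypes of each individual in cluster 1
  # (valued 1), totals 2 -> nothing to adjust
  local <- local_from_strings(c("00", "00", "00", "00"))
  g <- build_graph(local, c(2L, 2L))
  part_ok <- fake_partition(2, c(1L, 1L, 1L, 1L))
  adj <- adjust_unsatisfied(g, part_ok, fake_assignment(c(1L, 0L)),
                            c(2L, 2L), restarts = 3, seed = 4)
  expect_true(all(adj$satisfied))
  expect_identical(adj$partition$assignment, part_ok$assignment)
  expect_equal(unname(adj$copies), matrix(1L, 2, 2), ignore_attr = TRUE)

  # total 4 with cluster values {0,1,2}: the only summing pair is (2,2)
  local2 <- local_from_strings(c("0011", "1100", "0000", "1111", "0101",
                                 "1010"))
  g2 <- build_graph(local2, c(4L, 2L, 2L))
  part2 <- fake_partition(3, c(1L, 2L, 1L, 2L, 3L, 3L))
  part2$cut_value <- cut_weight(g2, part2$assignment)
  adj2 <- adjust_unsatisfied(g2, part2, fake_assignment(c(0L, 1L, 2L)),
                             c(4L, 2L, 2L), restarts = 3, seed = 6)
  expect_equal(unname(adj2$copies[1, ]), c(2L, 2L))
  # an unreachable total is flagged unresolved, not silently dropped
  adj3 <- adjust_unsatisfied(g2, part2, fake_assignment(c(0L, 1L, 2L)),
                             c(9L, 2L, 2L), restarts = 2, seed = 6)
  expect_equal(adj3$unresolved, 1L)
  expect_true(all(is.na(adj3$copies[1, ])))
})

test_that("the adjustment picks the cut-maximizing feasible re-placement", {
  set.seed(321)
  for (rep in 1:5) {
    sim <- simulate_panel(sim_config(ld_flip_fraction = 0.35,
                                     seed = 400 + rep))
    local <- select_window(sim$panel, sim$cnv, 1.0)
    g <- build_graph(local, sim$cnv)
    part <- greedy_constrained_maxkcut(g, 2, restarts = 5, seed = rep)
    cs <- build_constraints(part, as.integer(sim$cnv$totals))
    asg <- solve_unique_max2csp(cs, restarts = 5, seed = rep)
    adj <- adjust_unsatisfied(g, part, asg, as.integer(sim$cnv$totals),
                              restarts = 5, seed = rep)
    # final assignment satisfies every individual for whom a value pair exists
    vals <- asg$values
    vals[vals == -1L] <- NA_integer_
    sums <- outer(vals, vals, `+`)
    for (i in seq_along(sim$cnv$totals)) {
      reachable <- any(sums == sim$cnv$totals[i], na.rm = TRUE)
      expect_equal(adj$satisfied[i], reachable)
    }
  }
})

test_that("phase_cnvs skips sparse windows and reports reasons", {
  sim <- simulate_panel(sim_config(n_snps = 7L, seed = 55))
  res <- phase_cnvs(sim$panel, sim$cnv, min_snps = 10L, seed = 1)
  expect_equal(length(res$calls), 0L)
  expect_match(res$summary$status, "skipped: <10 SNPs")
  res2 <- phase_cnvs(sim$panel, sim$cnv, min_snps = 5L, seed = 1)
  expect_equal(res2$summary$status, "ok")
  expect_equal(nrow(res2$table), 16L)
})

test_that("the CLI phases files reproducibly", {
  skip_if_not_installed("optparse")
  dir <- tempfile()
  dir.create(dir)
  sim <- simulate_panel(sim_config(seed = 20))
  hap <- file.path(dir, "p.hap")
  cnvf <- file.path(dir, "c.tsv")
  write_haplotypes(sim$panel, hap)
  write_cnv_table(sim$cnv, cnvf)
  out1 <- file.path(dir, "calls1.tsv")
  out2 <- file.path(dir, "calls2.tsv")
  expect_equal(suppressMessages(run_cli(c("phase", "--hap", hap, "--cnv",
    cnvf, "--out", out1, "--seed", "7"))), 0L)
  expect_equal(suppressMessages(run_cli(c("phase", "--hap", hap, "--cnv",
    cnvf, "--out", out2, "--seed", "7"))), 0L)
  expect_identical(readLines(out1), readLines(out2))
  calls <- read_calls(out1)
  expect_true(all((calls$copy_hapA + calls$copy_hapB)[calls$satisfied] ==
                  calls$total[calls$satisfied]))
  # bad input exits non-zero instead of raising
  expect_equal(suppressMessages(run_cli(c("phase", "--hap", "missing.hap",
    "--cnv", cnvf, "--out", out1))), 1L)
})
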