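# Unique Max-2-CSP: constraint construction, counting, heuristic and oracle.

test_that("build_constraints turns cluster pairs into sum constraints", {
  # 3 individuals on k=3 clusters; individual 3's haplotypes sit in X1 and X3
  part <- fake_partition(3, c(1, 2, 2, 2, 1, 3))
  cs <- build_constraints(part, totals = c(3L, 2L, 2L))
  expect_s3_class(cs, "ConstraintSet")
  expect_true(any(cs$constraints$a == 1 & cs$constraints$b == 3 &
                  cs$constraints$T == 2))          # X1 + X3 = 2
  expect_true(any(cs$constraints$a == 2 & cs$constraints$b == 2 &
                  cs$constraints$T == 2))          # both haplotypes in X2
  expect_equal(sum(cs$constraints$N), 3L)
  expect_equal(cs$c_max, 3L)

  # identical constraints collapse with multiplicity
  part5 <- fake_partition(2, rep(c(1, 2), 5))
  cs5 <- build_constraints(part5, totals = rep(1L, 5))
  expect_equal(nrow(cs5$constraints), 1L)
  expect_equal(cs5$constraints$N, 5L)
})

test_that("count_satisfied counts multiplicities and ignores unassigned", {
  cs <- constraint_set(2, data.frame(a = 1, b = 2, T = 1, N = 3))
  expect_equal(count_satisfied(cs, c(0, 1)), 3L)
  expect_equal(count_satisfied(cs, c(0, -1)), 0L)
  cs2 <- constraint_set(2, data.frame(a = c(1, 1), b = c(2, 2),
                                      T = c(1, 3), N = c(2, 1)))
  expect_equal(count_satisfied(cs2, c(0, 1)), 2L)
  # order-independent: shuffled input rows give the same collapsed set
  cs2b <- constraint_set(2, data.frame(a = c(1, 1), b = c(2, 2),
                                       T = c(3, 1), N = c(1, 2)))
  expect_equal(cs2$constraints, cs2b$constraints)
})

test_that("the heuristic solves easy chains exactly", {
  # X1+X2=1 and X1+X3=2 over D={0,1,2}: only (0,1,2) satisfies both
  cs <- constraint_set(3, data.frame(a = c(1, 1), b = c(2, 3), T = c(1, 2)))
  asg <- solve_unique_max2csp(cs, restarts = 10, seed = 1)
  expect_equal(asg$values, c(0L, 1L, 2L))
  expect_equal(asg$satisfied_count, 2L)
})

test_that("distinctness forbids the 1,1 split of X1+X2=2", {
  cs <- constraint_set(2, data.frame(a = 1, b = 2, T = 2))
  for (s in 1:5) {
    asg <- solve_unique_max2csp(cs, restarts = 10, seed = s)
    expect_setequal(asg$values, c(0L, 2L))
    expect_equal(asg$satisfied_count, 1L)
  }
})

test_that("solution-table greedy leaves genuinely conflicting variables at -1", {
  # no propagation can reach X3 consistently with distinctness here:
  # 2*X3 = 2 forces X3 = 1, but X1+X2=1 wants 0/1 assigned first
  cs <- constraint_set(3, data.frame(a = c(1, 3), b = c(2, 3), T = c(1, 2),
                                     N = c(3, 1)))
  asg <- solve_unique_max2csp(cs, restarts = 10, seed = 4)
  expect_equal(asg$satisfied_count, 3L)
  vals <- asg$values
  expect_setequal(vals[1:2], c(0L, 1L))
  expect_true(vals[3] == -1L || !(vals[3] %in% vals[1:2]))
})

test_that("degenerate constraint sets are handled", {
  cs <- constraint_set(3, data.frame(a = integer(), b = integer(),
                                     T = integer(), N = integer()))
  asg <- solve_unique_max2csp(cs, seed = 1)
  expect_equal(asg$values, rep(-1L, 3))
  expect_equal(asg$satisfied_count, 0L)
  expect_equal(brute_force_max2csp(cs)$satisfied_count, 0L)
})

test_that("brute-force oracle matches hand enumeration", {
  cs1 <- constraint_set(2, data.frame(a = 1, b = 2, T = 1, N = 4))
  expect_equal(brute_force_max2csp(cs1)$satisfied_count, 4L)
  # contradictory targets: no injective assignment satisfies both types
  cs2 <- constraint_set(2, data.frame(a = c(1, 1), b = c(2, 2),
                                      T = c(1, 2), N = c(2, 2)))
  expect_equal(brute_force_max2csp(cs2)$satisfied_count, 2L)
  expect_error(brute_force_max2csp(constraint_set(
    7, data.frame(a = 1, b = 2, T = 1))), "6 variables")
})

test_that("heuristic is sound (never beats the oracle) and always distinct", {
  set.seed(500)
  for (rep in 1:40) {
    cs <- random_cs(sample(2:5, 1))
    asg <- solve_unique_max2csp(cs, restarts = 5, seed = rep)
    opt <- brute_force_max2csp(cs)$satisfied_count
    expect_lte(asg$satisfied_count, opt)
    assigned <- asg$values[asg$values != -1L]
    expect_equal(anyDuplicated(assigned), 0L)
    expect_equal(count_satisfied(cs, asg$values), asg$satisfied_count)
  }
})

test_that("heuristic attains the optimum on planted conflict-free instances", {
  set.seed(600)
  for (rep in 1:25) {
    pl <- planted_cs(sample(3:5, 1))
    asg <- solve_unique_max2csp(pl$cs, restarts = 10, seed = rep)
    opt <- brute_force_max2csp(pl$cs)$satisfied_count
    expect_equal(opt, sum(pl$cs$constraints$N))   # consistent by construction
    expect_equal(asg$satisfied_count, opt)
  }
})

test_that("domain bound honours both c_max and the n-1 requirement", {
  cs <- constraint_set(5, data.frame(a = 1, b = 2, T = 1))
  expect_equal(cs$d, 4L)    # n - 1 > c_max
  cs2 <- constraint_set(2, data.frame(a = 1, b = 2, T = 6))
  expect_equal(cs2$d, 6L)   # c_max > n - 1
  asg <- solve_unique_max2csp(cs2, restarts = 5, seed = 2)
  expect_equal(sum(asg$values[asg$values >= 0]), 6L)
})
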