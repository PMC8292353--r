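test_that("threshold cascade completes K5 in one step from two seeds", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  tr <- run_threshold_model(g, th, seeds = c("1", "2"))
  expect_setequal(active_nodes(tr), as.character(1:5))
  expect_equal(max(tr$activation_time), 1)
  expect_equal(unname(tr$activation_time[c("1", "2")]), c(0, 0))
})

test_that("star at T = 2 activates only the center beyond the seeded leaves", {
  g <- star_graph(5)
  th <- assign_thresholds(g, "absolute", 2)
  tr <- run_threshold_model(g, th, seeds = c("l1", "l2"))
  expect_setequal(active_nodes(tr), c("l1", "l2", "c"))
  expect_true(all(is.na(tr$activation_time[c("l3", "l4", "l5")])))
})

test_that("no seeds means no activity", {
  g <- random_graph(20, 0.2, 1)
  th <- assign_thresholds(g, "absolute", 2)
  tr <- run_threshold_model(g, th, seeds = character(0))
  expect_length(active_nodes(tr), 0)
  expect_equal(tr$steps, 0L)
})

test_that("T = 1 reduces to component reachability", {
  g <- random_graph(40, 0.05, 3)
  th <- assign_thresholds(g, "absolute", 1)
  seeds <- c("1", "25")
  tr <- run_threshold_model(g, th, seeds)
  comps <- igraph::components(g)
  expected <- igraph::V(g)$name[comps$membership %in%
                                  comps$membership[match(seeds, igraph::V(g)$name)]]
  expect_setequal(active_nodes(tr), expected)
})

test_that("final active set is monotone in the seed set", {
  for (s in 1:20) {
    g <- random_graph(25, 0.15, s)
    th <- assign_thresholds(g, "absolute", 2)
    nm <- igraph::V(g)$name
    a <- withr::with_seed(s, sample(nm, 3))
    b <- union(a, withr::with_seed(s + 100, sample(nm, 3)))
    act_a <- active_nodes(run_threshold_model(g, th, a))
    act_b <- active_nodes(run_threshold_model(g, th, b))
    expect_true(all(act_a %in% act_b))
  }
})

test_that("independent cascade limits: theta 0 stays at seeds, theta 1 fills components", {
  g <- random_graph(30, 0.1, 5)
  tr0 <- run_independent_cascade(g, 0, seeds = c("1", "2"), rng_seed = 1)
  expect_setequal(active_nodes(tr0), c("1", "2"))
  tr1 <- run_independent_cascade(g, 1, seeds = "1", rng_seed = 1)
  comps <- igraph::components(g)
  expected <- igraph::V(g)$name[comps$membership == comps$membership[1]]
  expect_setequal(active_nodes(tr1), expected)
})

test_that("independent cascade hits a two-hop target at theta squared", {
  g <- path_graph(c("a", "b", "c"))
  hits <- vapply(1:2000, function(s) {
    "c" %in% active_nodes(run_independent_cascade(g, 0.5, "a", rng_seed = s))
  }, logical(1))
  # P(c active) = 0.5^2; Monte-Carlo tolerance 3 SE
  expect_lt(abs(mean(hits) - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
})

test_that("linear threshold model covers its degenerate and forced cases", {
  g <- star_graph(4)
  tr_all <- run_linear_threshold(g, seeds = igraph::V(g)$name, rng_seed = 1)
  expect_true(all(tr_all$activation_time == 0))
  # center active => each leaf's full incoming weight is 1 >= its uniform draw
  tr <- run_linear_threshold(g, seeds = "c", rng_seed = 2)
  expect_setequal(active_nodes(tr), igraph::V(g)$name)
  tr0 <- run_linear_threshold(g, seeds = character(0), rng_seed = 3)
  expect_length(active_nodes(tr0), 0)
})

test_that("clustered seed sets grow outward from the focal node", {
  g <- path_graph(c("a", "b", "c", "d"))
  expect_identical(build_seed_set(g, "a", 1), "a")
  # b is the only neighbour, then c is the only node adjacent to {a, b}
  expect_setequal(build_seed_set(g, "a", 3, rng_seed = 1), c("a", "b", "c"))
  s <- star_graph(5)
  ss <- build_seed_set(s, "c", 3, rng_seed = 1)
  expect_equal(ss[1], "c")
  expect_true(all(ss[-1] %in% paste0("l", 1:5)))
  expect_warning(build_seed_set(g, "a", 10, rng_seed = 1), "not reachable")
  expect_error(build_seed_set(g, "a", 0), ">= 1")
})

test_that("cascade outcome applies the inclusive global-cascade cutoff", {
  g <- k5()
  th <- assign_thresholds(g, "absolute", 2)
  tr <- run_threshold_model(g, th, seeds = c("1", "2"))
  out <- cascade_outcome(tr)
  expect_equal(out$adoption_fraction, 1)
  expect_true(out$is_global_cascade)

  out2 <- cascade_outcome(tr, n = 100)
  expect_equal(out2$adoption_fraction, 0.05)
  expect_false(out2$is_global_cascade)

  out3 <- cascade_outcome(tr, n = 10, cascade_fraction = 0.5)
  expect_true(out3$is_global_cascade)  # boundary inclusive
})
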