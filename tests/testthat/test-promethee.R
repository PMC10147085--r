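test_that("the six preference functions match their closed forms", {
  expect_equal(preference_value(0, pref_fn("usual")), 0)
  expect_equal(preference_value(1e-9, pref_fn("usual")), 1)
  expect_equal(preference_value(1, pref_fn("gaussian", s = 1)),
               1 - exp(-0.5), tolerance = 1e-12)
  expect_equal(preference_value(0.25, pref_fn("v_shape", p = 0.5)), 0.5)
  expect_equal(preference_value(0.8, pref_fn("v_shape", p = 0.5)), 1)
  expect_equal(preference_value(c(0.05, 0.3, 0.9),
                                pref_fn("level", q = 0.1, p = 0.6)),
               c(0, 0.5, 1))
  expect_equal(preference_value(c(0.05, 0.35, 0.9),
                                pref_fn("linear", q = 0.1, p = 0.6)),
               c(0, 0.5, 1))
  expect_equal(preference_value(0.1, pref_fn("u_shape", q = 0.1)), 0)
  expect_equal(preference_value(0.11, pref_fn("u_shape", q = 0.1)), 1)
  # no preference without strict advantage, for every family
  specs <- list(pref_fn("usual"), pref_fn("u_shape", q = 0.1),
                pref_fn("v_shape", p = 1), pref_fn("level", q = 0.1, p = 1),
                pref_fn("linear", q = 0.1, p = 1), pref_fn("gaussian", s = 1))
  for (sp in specs) expect_equal(preference_value(c(-0.3, 0), sp), c(0, 0))
})

test_that("preference values stay in [0,1] and are nondecreasing in d", {
  d <- seq(-1, 2, by = 0.01)
  specs <- list(pref_fn("usual"), pref_fn("u_shape", q = 0.2),
                pref_fn("v_shape", p = 0.7),
                pref_fn("level", q = 0.2, p = 0.9),
                pref_fn("linear", q = 0.2, p = 0.9),
                pref_fn("gaussian", s = 0.5))
  for (sp in specs) {
    v <- preference_value(d, sp)
    expect_true(all(v >= 0 & v <= 1))
    expect_true(all(diff(v) >= -1e-15))
  }
})

test_that("invalid preference specifications are rejected", {
  expect_error(pref_fn("linear", q = 0.5, p = 0.2), "exceed q")
  expect_error(pref_fn("gaussian", s = 0), "must be > 0")
  expect_error(pref_fn("u_shape"), "needs `q`")
  expect_error(pref_fn("banana"))
})

test_that("preference index handles ties, dominance and split criteria", {
  sc <- default_scale()
  # identical rating vectors: zero preference both ways
  pi_fx <- preference_index(fx_crisp)
  expect_equal(pi_fx["[11C]RO-643", "[11C]RO-963"], 0)
  expect_equal(pi_fx["[18F]THK5105", "[18F]THK5117"], 0)
  expect_true(all(diag(pi_fx) == 0))
  expect_true(all(pi_fx >= 0 & pi_fx <= 1))

  # single criterion, weight 1, usual: strict winner gets the full index
  m1 <- decision_matrix(matrix(c("H", "L"), 2, 1,
                               dimnames = list(c("a", "b"), NULL)),
                        list(criterion("c1", weight = "H")))
  pi1 <- preference_index(crispify(m1, sc))
  expect_equal(pi1["a", "b"], 1)
  expect_equal(pi1["b", "a"], 0)

  # two equally weighted criteria split between the alternatives
  m2 <- decision_matrix(matrix(c("H", "L", "L", "H"), 2, 2,
                               dimnames = list(c("a", "b"), NULL)),
                        list(criterion("c1", weight = 1),
                             criterion("c2", weight = 1)))
  pi2 <- preference_index(crispify(m2, sc))
  expect_equal(pi2["a", "b"], 0.5)
  expect_equal(pi2["b", "a"], 0.5)

  expect_error(preference_index(crispify(m1, sc)[
    c("values", "weights")]), "crisp_matrix")
})

test_that("vectorized flows equal the triple-loop oracle on random problems", {
  specs <- list(pref_fn("usual"), pref_fn("gaussian", s = 0.4),
                pref_fn("linear", q = 0.1, p = 0.5),
                pref_fn("level", q = 0.05, p = 0.3))
  for (seed in 1:6) {
    n <- 3 + seed %% 4; k <- 2 + seed %% 3
    sp <- specs[[1 + seed %% length(specs)]]
    m <- generate_random_problem(n, k, seed = seed, pref_fn = sp)
    cm <- crispify(m)
    f <- outranking_flows(preference_index(cm))
    orc <- oracle_flows(cm$values, cm$weights, cm$directions, sp)
    expect_equal(f$phi_plus, unname(orc$plus), tolerance = 1e-12)
    expect_equal(f$phi_minus, unname(orc$minus), tolerance = 1e-12)
    expect_flow_table_valid(f)
  }
})

test_that("a weakly dominant alternative has zero weakness and rank 1", {
  # holds for any preference function and any nonnegative weights
  specs <- list(pref_fn("usual"), pref_fn("gaussian", s = 2),
                pref_fn("v_shape", p = 0.5),
                pref_fn("linear", q = 0.05, p = 0.8))
  for (sp in specs) {
    res <- promethee(fx$matrix, fx$scale, specs = sp)
    f <- res$flows
    expect_equal(f$phi_minus[f$alternative == "[18F]RO-948"], 0)
    expect_equal(f$rank[f$alternative == "[18F]RO-948"], 1L)
    expect_equal(f$phi_plus[f$alternative == "[18F]THK5105"], 0)
    expect_equal(f$phi_plus[f$alternative == "[18F]THK5117"], 0)
  }
})

test_that("improving one cell of a maximize criterion never lowers phi_net", {
  ladder <- c("VL", "L", "M", "H", "VH")
  for (seed in 1:4) {
    m <- generate_random_problem(5, 3, seed = seed,
                                 pref_fn = pref_fn("gaussian", s = 0.5))
    j <- which(vapply(m$criteria, `[[`, character(1), "direction") ==
                 "max")[1]
    if (is.na(j)) { m$criteria[[1]]$direction <- "max"; j <- 1 }
    cur <- m$cells[2, j]
    pos <- match(cur, ladder)
    if (pos == length(ladder)) next
    net0 <- promethee(m)$flows
    m$cells[2, j] <- ladder[pos + 1]
    net1 <- promethee(m)$flows
    a <- m$alternatives[2]
    expect_gte(net1$phi_net[net1$alternative == a] -
                 net0$phi_net[net0$alternative == a], -1e-12)
  }
})

test_that("PROMETHEE I classifies preference, indifference, incomparability", {
  f <- structure(data.frame(
    alternative = c("a", "b", "c", "d"),
    phi_plus = c(0.6, 0.2, 0.5, 0.6),
    phi_minus = c(0.1, 0.5, 0.4, 0.1)),
    class = c("flow_table", "data.frame"))
  f$phi_net <- f$phi_plus - f$phi_minus
  rel <- promethee1_relations(f)
  expect_equal(unname(diag(rel)), rep("self", 4))
  expect_equal(rel["a", "b"], "P")     # stronger and less weak
  expect_equal(rel["b", "a"], "-")
  expect_equal(rel["a", "d"], "I")     # both flows tie
  expect_equal(rel["d", "a"], "I")
  expect_equal(rel["c", "b"], "P")     # phi+ higher, phi- lower
  expect_equal(rel["a", "c"], "P")
  # build a genuine incomparability: strong on one side, weak on the other
  f2 <- structure(data.frame(
    alternative = c("x", "y"),
    phi_plus = c(0.7, 0.3), phi_minus = c(0.6, 0.1)),
    class = c("flow_table", "data.frame"))
  f2$phi_net <- f2$phi_plus - f2$phi_minus
  rel2 <- promethee1_relations(f2)
  expect_equal(rel2["x", "y"], "R")    # both flows strictly greater
  expect_equal(rel2["y", "x"], "R")
})

test_that("duplicated rating vectors are indifferent and share a rank", {
  res <- promethee(fx$matrix, fx$scale)
  rel <- res$relations
  expect_equal(rel["[11C]RO-643", "[11C]RO-963"], "I")
  expect_equal(rel["[18F]THK5105", "[18F]THK5117"], "I")
  f <- res$flows
  r643 <- f$rank[f$alternative == "[11C]RO-643"]
  r963 <- f$rank[f$alternative == "[11C]RO-963"]
  expect_equal(r643, r963)
  # competition ranking: the rank after a tie is offset by the tie count
  expect_equal(sort(f$rank), c(1, 2, 2, 4, 5, 6, 7, 7, 9, 10, 11, 12, 13,
                               14, 14))
})

test_that("two alternatives with one dominant rank (1, 2)", {
  m <- decision_matrix(matrix(c("VH", "L", "H", "M"), 2, 2,
                              dimnames = list(c("good", "bad"), NULL)),
                       list(criterion("c1", weight = "H"),
                            criterion("c2", weight = "M")))
  f <- promethee(m)$flows
  expect_equal(f$rank[f$alternative == "good"], 1L)
  expect_equal(f$rank[f$alternative == "bad"], 2L)
})

test_that("usual-function rankings are invariant to affine column rescaling", {
  m <- generate_random_problem(5, 3, seed = 9)
  cm <- crispify(m)
  f0 <- promethee2_rank(outranking_flows(preference_index(cm)))
  cm2 <- cm
  cm2$values[, 2] <- 5 + 3 * cm2$values[, 2]  # positive affine map
  f1 <- promethee2_rank(outranking_flows(preference_index(cm2)))
  merged <- merge(f0, f1, by = "alternative")
  expect_equal(merged$rank.x, merged$rank.y)
})

test_that("unicriterion flows reconstruct the net flow and flag flat criteria", {
  for (seed in c(2, 5)) {
    m <- generate_random_problem(6, 4, seed = seed,
                                 pref_fn = pref_fn("gaussian", s = 0.5))
    cm <- crispify(m)
    phi <- unicriterion_net_flows(cm)
    f <- outranking_flows(preference_index(cm))
    expect_equal(unname(drop(phi %*% cm$weights)), f$phi_net,
                 tolerance = 1e-12)
  }
  # a criterion rated identically everywhere contributes nothing
  m <- generate_random_problem(5, 2, seed = 1)
  m$cells[, 2] <- "M"
  phi <- unicriterion_net_flows(crispify(m))
  expect_equal(unname(phi[, 2]), rep(0, 5))
  # the dominant fixture alternative has no per-criterion weakness
  phi_fx <- unicriterion_net_flows(fx_crisp)
  expect_true(all(phi_fx["[18F]RO-948", ] >= 0))
})
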