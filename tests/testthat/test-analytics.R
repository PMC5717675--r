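test_that("weighted fractions follow the degree-times-fitness node sums", {
  st <- make_state(c(1, 2, 2, 2))
  g <- path4()
  qf <- weighted_fraction(st, g, c(1, 2, 2, 1))      # f_k = k
  expect_equal(unname(qf[1]), 0.1)                   # 1 / (1+4+4+1)
  expect_equal(unname(opinion_fractions(st)[1]), 0.25)
  expect_equal(sum(qf), 1)

  all2 <- make_state(rep(2, 5), n_opinions = 3)
  qf2 <- weighted_fraction(all2, igraph::make_ring(5), rep(1, 5))
  expect_equal(unname(qf2), c(0, 1, 0))
})

test_that("inverse-degree fitness collapses the weighted fraction onto q", {
  g <- generate_ba_network(300, 3, seed = 15)
  f <- resolve_fitness(fitness_model("inverse_degree"), g)$node
  for (s in 1:5) {
    st <- initialize_opinions(g, 4, seed = s)
    expect_equal(unname(weighted_fraction(st, g, f)),
                 unname(opinion_fractions(st)), tolerance = 1e-12)
  }
})

test_that("committed weighted fractions restrict the weights to zealots", {
  g <- path4()
  st0 <- make_state(c(1, 2, 2, 2))
  expect_equal(unname(committed_weighted_fraction(st0, g, rep(1, 4))), c(0, 0))
  st1 <- make_state(c(1, 2, 1, 1), committed_ids = 2)
  sf <- committed_weighted_fraction(st1, g, rep(1, 4))
  expect_equal(unname(sf[2]), 1 / 3)                 # degree 2 of total degree 6
  stall <- make_state(rep(1, 4), committed_ids = 1:4)
  expect_equal(unname(committed_weighted_fraction(stall, g, rep(1, 4))[1]), 1)
})

test_that("fixation probabilities equal initial weighted fractions and guard preconditions", {
  g <- igraph::make_ring(8)                          # regular: q^f = q
  st <- make_state(c(1, 1, 1, 2, 2, 2, 2, 2))
  expect_equal(unname(fixation_probabilities(st, g, rep(1, 8))), c(3, 5) / 8)
  cons <- make_state(rep(1, 8), n_opinions = 2)
  expect_equal(unname(fixation_probabilities(cons, g, rep(1, 8))), c(1, 0))
  stc <- make_state(c(1, 1, 1, 2, 2, 2, 2, 2), committed_ids = 1)
  expect_error(fixation_probabilities(stc, g, rep(1, 8)), "committed")
  expect_error(fixation_probabilities(st, g, rep(1, 8), media = media_field(1, 0.5)),
               "media")
})

test_that("committed steady states match the closed form and hand values", {
  pr <- predict_steady_state(s = c(0.2, 0.1), sf = c(0.3, 0.1))
  expect_equal(pr$q_inf, c(0.725, 0.275))
  expect_equal(pr$qf_inf, c(0.75, 0.25))

  # all committed on one opinion: it takes the whole population
  pr1 <- predict_steady_state(s = c(0.3, 0), sf = c(0.4, 0))
  expect_equal(pr1$q_inf, c(1, 0))

  # symmetric committed sets split evenly
  prs <- predict_steady_state(s = c(0.2, 0.2, 0), sf = c(0.15, 0.15, 0))
  expect_equal(prs$q_inf[1], prs$q_inf[2])
  expect_equal(prs$q_inf[3], 0)

  # realized-network wrapper agrees with the formula on its own fractions
  g <- generate_ba_network(400, 3, seed = 18)
  st <- initialize_opinions(g, 3, seed = 18)
  st <- designate_committed(st, g, data.frame(opinion = c(1, 2), fraction = c(0.2, 0.1),
                                              hub_count = c(5, 0)), seed = 18)
  f <- resolve_fitness(fitness_model("power", exponent = 0.5), g)$node
  pred <- steady_state_committed(st, g, f)
  s <- committed_fractions(st)
  sf <- committed_weighted_fraction(st, g, f)
  expect_equal(pred$q_inf, unname(s + (1 - sum(s)) * sf / sum(sf)))
  expect_error(steady_state_committed(initialize_opinions(g, 3, seed = 1), g, f),
               "fixation_probabilities")
})

test_that("media steady states reduce to the committed form at P = 0 and obey the P = 1 limits", {
  s <- c(0.2, 0.2, 0, 0, 0)
  sf <- c(0.5, 0.1, 0, 0, 0)
  p0 <- predict_steady_state(s, sf, P = 0)
  pm0 <- predict_steady_state(s, sf, P = 0, media_opinion = 2)
  expect_identical(p0$q_inf, pm0$q_inf)

  # P = 1 with media on a committed opinion: q1 = s1 = 0.2, q2 = 0.8
  p1 <- predict_steady_state(s, sf, P = 1, media_opinion = 2)
  expect_equal(p1$q_inf[1], 0.2)
  expect_equal(p1$q_inf[2], 0.8)
  # P = 1 with media on an uncommitted opinion: q3 = 1 - s = 0.6
  p3 <- predict_steady_state(s, sf, P = 1, media_opinion = 3)
  expect_equal(p3$q_inf[3], 0.6)
  expect_equal(p3$q_inf[1:2], c(0.2, 0.2))

  expect_error(predict_steady_state(s, sf, P = 0.5), "media opinion")
})

test_that("steady-state predictions are normalized over random scenarios", {
  set.seed(31)
  for (r in 1:1000) {
    I <- sample(2:6, 1)
    s <- stats::runif(I, 0, 0.8 / I)
    sf <- s * stats::runif(I, 0.2, 3)
    P <- stats::runif(1)
    m <- sample(I, 1)
    pr <- predict_steady_state(s, sf, P = P, media_opinion = m)
    expect_equal(sum(pr$q_inf), 1, tolerance = 1e-12)
    expect_equal(sum(pr$qf_inf), 1, tolerance = 1e-12)
    expect_true(all(pr$q_inf >= -1e-15 & pr$q_inf <= 1 + 1e-15))
  }
})

test_that("the media decomposition sums to the media opinion's share", {
  s <- c(0.2, 0.2, 0, 0, 0)
  sf <- c(0.5, 0.1, 0, 0, 0)
  for (P in c(0.1, 0.5, 0.9)) {
    dec <- decompose_media_share(s, sf, P, media_opinion = 2)
    pr <- predict_steady_state(s, sf, P = P, media_opinion = 2)
    expect_equal(sum(dec$value), pr$q_inf[2], tolerance = 1e-12)
    expect_true(all(dec$value >= 0))
  }
  # P -> 1: the media-attributable parts approach 1 - s = 0.6
  dec1 <- decompose_media_share(s, sf, 1, media_opinion = 2)
  media_parts <- sum(dec1$value[dec1$part %in% c("media_direct", "media_via_network")])
  expect_equal(media_parts, 0.6)
  # P = 0: no media influence
  dec0 <- decompose_media_share(s, sf, 0, media_opinion = 2)
  expect_equal(sum(dec0$value[dec0$part %in% c("media_direct", "media_via_network")]), 0)
  # media opinion without committed holders: only media parts remain
  dec3 <- decompose_media_share(s, sf, 0.4, media_opinion = 3)
  expect_equal(dec3$value[dec3$part == "committed"], 0)
  expect_equal(dec3$value[dec3$part == "network_amplification"], 0)
})

test_that("the critical media strength matches the hand-derived crossing", {
  # s1 = s2 = 0.2, s1^f = 0.5, s2^f = 0.1, media 2 vs rival 1: P* = 2/7
  ps <- critical_strength(c(0.2, 0.2), c(0.5, 0.1), media_opinion = 2,
                          rival_opinion = 1)
  expect_equal(ps, 2 / 7, tolerance = 1e-8)
  # symmetric committed support: crossing sits at the P = 0 boundary
  expect_equal(critical_strength(c(0.2, 0.2), c(0.3, 0.3), 2, 1), 0)
  # rival without support: media dominates everywhere
  expect_error(critical_strength(c(0, 0.2), c(0, 0.3), 2, 1), "media opinion dominates")
  expect_error(critical_strength(c(0.2, 0.2), c(0.5, 0.1), 2, 2), "differ")
})

test_that("media share is monotone in P, rival share anti-monotone", {
  s <- c(0.2, 0.2, 0, 0, 0)
  sf <- c(0.55, 0.08, 0, 0, 0)
  grid <- seq(0.001, 1, length.out = 101)
  qm <- vapply(grid, function(P) predict_steady_state(s, sf, P, 2)$q_inf[2], numeric(1))
  qr <- vapply(grid, function(P) predict_steady_state(s, sf, P, 2)$q_inf[1], numeric(1))
  expect_true(all(diff(qm) >= -1e-12))
  expect_true(all(diff(qr) <= 1e-12))
})

test_that("weighted-network fractions equal k^theta fitness fractions", {
  st <- make_state(c(1, 2, 2, 2))
  g <- path4()
  # node weights k^(theta+1): degrees (1,2,2,1) -> (1,4,4,1), opinion 1 holds node 1
  expect_equal(unname(weighted_equivalence_qf(st, g, theta = 1)[1]), 0.1)
  expect_equal(weighted_equivalence_qf(st, g, theta = 0),
               weighted_fraction(st, g, rep(1, 4)))
  gb <- generate_ba_network(200, 3, seed = 25)
  deg <- igraph::degree(gb)
  for (s in 1:5) {
    stb <- initialize_opinions(gb, 3, seed = s)
    expect_equal(weighted_equivalence_qf(stb, gb, theta = 0.4),
                 weighted_fraction(stb, gb, deg^0.4), tolerance = 1e-12)
  }
})

test_that("amplification factors normalize committed weighted fractions", {
  g <- generate_ba_network(300, 3, seed = 28)
  st <- initialize_opinions(g, 3, seed = 28)
  st <- designate_committed(st, g, data.frame(opinion = c(1, 2), fraction = c(0.15, 0.1),
                                              hub_count = c(10, 0)), seed = 28)
  f <- resolve_fitness(fitness_model("power", exponent = 0.5), g)$node
  amp <- amplification_factor(st, g, f)
  sf <- committed_weighted_fraction(st, g, f)
  expect_equal(unname(amp), unname(sf / sum(sf)))
  expect_equal(unname(amp[3]), 0)
  # Eq-style identity: q_inf - s = (1 - s) * factor
  pred <- steady_state_committed(st, g, f)
  s <- committed_fractions(st)
  expect_equal(pred$q_inf - unname(s), (1 - sum(s)) * unname(amp), tolerance = 1e-12)
  st_single <- make_state(c(1, 1, 2, 2), committed_ids = 1)
  expect_equal(unname(amplification_factor(st_single, path4(), rep(1, 4))), c(1, 0))
  expect_error(amplification_factor(make_state(c(1, 2, 1, 2)), path4(), rep(1, 4)),
               "no committed")
})
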