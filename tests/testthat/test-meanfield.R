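test_that("class-level weighted fractions match their node-sum twin", {
  # single degree class: q^f collapses onto q
  cls1 <- degree_class_state(degrees = 4, p = 1, q = matrix(c(0.3, 0.7)),
                             fitness = 2)
  expect_equal(qf_from_classes(cls1), c(0.3, 0.7))

  # two classes, f = k: direct evaluation
  cls2 <- degree_class_state(degrees = c(1, 2), p = c(0.5, 0.5),
                             q = matrix(c(1, 0, 0, 1), 2, 2),
                             fitness = c(1, 2))
  expect_equal(qf_from_classes(cls2)[1], 0.5 / 2.5)

  # realized network: degree-class form == node-sum form
  g <- generate_ba_network(300, 3, seed = 33)
  st <- initialize_opinions(g, 4, seed = 33)
  f <- resolve_fitness(fitness_model("power", exponent = 0.5), g)$node
  cls <- degree_class_tables(st, g, f)
  expect_equal(qf_from_classes(cls), unname(weighted_fraction(st, g, f)),
               tolerance = 1e-12)
  # uniform fitness: reduces to the degree-weighted fraction
  clsu <- degree_class_tables(st, g, rep(1, 300))
  expect_equal(qf_from_classes(clsu), unname(weighted_fraction(st, g, rep(1, 300))),
               tolerance = 1e-12)
})

test_that("per-class transition probabilities follow the printed forms", {
  # p_k = 0.5, q_{1,k=1} = 0.2, classes arranged so q_1^f = 0.4 exactly:
  # gain = 0.5 * 0.8 * 0.4 = 0.16, loss = 0.5 * 0.2 * 0.6 = 0.06
  cls <- degree_class_state(degrees = c(1, 2), p = c(0.5, 0.5),
                            q = matrix(c(0.2, 0.8, 0.5, 0.5), 2, 2),
                            fitness = c(1, 1))
  expect_equal(qf_from_classes(cls)[1], 0.4)
  tp <- transition_probabilities(cls, 1, 1)
  expect_equal(tp$gain, 0.16)
  expect_equal(tp$loss, 0.06)

  # committed-saturated class: gains and losses vanish
  clss <- degree_class_state(degrees = c(1, 2), p = c(0.5, 0.5),
                             q = matrix(c(0.5, 0.5, 0.6, 0.4), 2, 2),
                             s = matrix(c(0.5, 0.5, 0, 0), 2, 2),
                             fitness = c(1, 1))
  tps <- transition_probabilities(clss, 1, 1)
  expect_equal(tps$gain, 0)
  expect_equal(tps$loss, 0)
  expect_error(transition_probabilities(cls, 7, 1), "not present")
})

test_that("the ODE flow conserves per-class normalization and has the right fixed points", {
  for (r in 1:20) {
    cls <- random_class_state(I = 3, K = 4, seed = r, committed = (r %% 2 == 0))
    rhs <- meanfield_rhs(cls)
    expect_lt(max(abs(colSums(rhs))), 1e-14)
    med <- media_field(opinion = 2, strength = 0.4)
    rhsm <- meanfield_rhs(cls, med)
    expect_lt(max(abs(colSums(rhsm))), 1e-14)
  }

  # consensus manifold: q_{i,k} = q_i^f for all k is stationary without committed
  qf <- c(0.25, 0.75)
  cls0 <- degree_class_state(degrees = c(2, 5), p = c(0.6, 0.4),
                             q = matrix(qf, 2, 2), fitness = c(1, 1))
  expect_lt(max(abs(meanfield_rhs(cls0))), 1e-14)

  # committed fixed point: q_{i,k} = (1 - sum_j s_{j,k}) q_i^f(inf) + s_{i,k}
  cls <- random_class_state(I = 3, K = 4, seed = 5, committed = TRUE)
  ss <- meanfield_steady_state(cls)
  cls_star <- cls
  cls_star$q <- ss$q_class
  expect_lt(max(abs(meanfield_rhs(cls_star))), 1e-12)
  # and under media
  med <- media_field(opinion = 1, strength = 0.3)
  ssm <- meanfield_steady_state(cls, med)
  cls_star$q <- ssm$q_class
  expect_lt(max(abs(meanfield_rhs(cls_star, med))), 1e-12)
})

test_that("the weighted fraction obeys dqf/dt = s^f - qf * sum(s^f) under the flow", {
  cls <- random_class_state(I = 3, K = 5, seed = 9, committed = TRUE)
  wk <- cls$degrees * cls$fitness * cls$p
  qf <- qf_from_classes(cls)
  sf <- as.numeric(cls$s %*% wk) / sum(wk)
  dqf_chain <- as.numeric(meanfield_rhs(cls) %*% wk) / sum(wk)
  expect_equal(dqf_chain, sf - qf * sum(sf), tolerance = 1e-12)
})

test_that("integration matches the analytic exponential relaxation without committed agents", {
  cls <- random_class_state(I = 3, K = 4, seed = 12, committed = FALSE)
  qf0 <- qf_from_classes(cls)
  traj <- integrate_meanfield(cls, t_end = 5, step = 0.01)
  arr <- attr(traj, "class_array")
  times <- attr(traj, "times")
  for (tt in c(1, 2, 5)) {
    idx <- which.min(abs(times - tt))
    analytic <- matrix(qf0, 3, 4) + (cls$q - matrix(qf0, 3, 4)) * exp(-times[idx])
    expect_lt(max(abs(arr[, , idx] - analytic)), 1e-6)
  }
  # qf is conserved along the numerical trajectory
  qf_path <- tapply(traj$qf, traj$opinion, function(x) max(abs(x - x[1])))
  expect_lt(max(qf_path), 1e-6)
  # t_end = 0 returns the initial state
  tr0 <- integrate_meanfield(cls, t_end = 0, step = 0.05)
  expect_equal(unique(tr0$time), 0)
  expect_equal(tr0$q, as.numeric(cls$q %*% cls$p))
})

test_that("integration converges to the closed-form fixed points", {
  cls <- random_class_state(I = 3, K = 4, seed = 14, committed = TRUE)
  ss <- meanfield_steady_state(cls)
  traj <- integrate_meanfield(cls, t_end = 80, step = 0.01)
  arr <- attr(traj, "class_array")
  expect_lt(max(abs(arr[, , dim(arr)[3]] - ss$q_class)), 1e-6)

  med <- media_field(opinion = 2, strength = 0.6)
  ssm <- meanfield_steady_state(cls, med)
  trajm <- integrate_meanfield(cls, med, t_end = 80, step = 0.01)
  arrm <- attr(trajm, "class_array")
  expect_lt(max(abs(arrm[, , dim(arrm)[3]] - ssm$q_class)), 1e-6)
})

test_that("mean-field steady states agree with the realized-network analytics", {
  for (r in 1:25) {
    g <- generate_ba_network(200, 3, seed = 40 + r)
    st <- initialize_opinions(g, 3, seed = r)
    st <- designate_committed(st, g,
                              data.frame(opinion = c(1, 2), fraction = c(0.15, 0.1),
                                         hub_count = c(3, 0)), seed = r)
    f <- resolve_fitness(fitness_model("power", exponent = 0.5), g)$node
    cls <- degree_class_tables(st, g, f)
    mf <- meanfield_steady_state(cls)$prediction
    an <- steady_state_committed(st, g, f)
    expect_equal(mf$q_inf, an$q_inf, tolerance = 1e-12)
    expect_equal(mf$qf_inf, an$qf_inf, tolerance = 1e-12)
    med <- media_field(opinion = 2, strength = 0.35)
    mfm <- meanfield_steady_state(cls, med)$prediction
    anm <- steady_state_media(st, g, f, med)
    expect_equal(mfm$q_inf, anm$q_inf, tolerance = 1e-12)
  }

  # all committed on opinion 1: every class saturates at 1
  g <- igraph::make_ring(10)
  st <- initialize_opinions(g, 2, seed = 1)
  st <- designate_committed(st, g, data.frame(opinion = 1, fraction = 1), seed = 1)
  cls <- degree_class_tables(st, g, rep(1, 10))
  expect_true(all(meanfield_steady_state(cls)$q_class[1, ] == 1))

  # pure regime is signalled distinctly
  st0 <- initialize_opinions(g, 2, seed = 1)
  cls0 <- degree_class_tables(st0, g, rep(1, 10))
  expect_error(meanfield_steady_state(cls0), "conserved regime")
})

test_that("the Fig-5 parameter set at P = 1 pins the committed share", {
  s <- matrix(0, 5, 2)
  s[1, ] <- 0.2; s[2, ] <- 0.2
  q <- matrix(0.2, 5, 2)
  cls <- degree_class_state(degrees = c(3, 6), p = c(0.5, 0.5), q = q, s = s,
                            fitness = c(1, 1))
  ss <- meanfield_steady_state(cls, media_field(opinion = 2, strength = 1))
  expect_equal(ss$prediction$q_inf[1], 0.2)
  expect_equal(ss$prediction$q_inf[2], 0.8)
})

test_that("ensemble trajectories track the integrated mean field", {
  sp <- study_scenario("fig2a", scale = 0.2, seed = 1)
  sp$horizon <- 30
  real <- realize_scenario(sp)
  cls <- degree_class_tables(real$state, real$graph, real$fitness$node)
  mft <- integrate_meanfield(cls, t_end = 30, step = 0.05)
  en <- run_ensemble(sp, 60)
  mf_at <- function(tt, i) mft$q[mft$opinion == i & abs(mft$time - tt) < 1e-9]
  for (tt in c(1, 2, 5, 10, 20, 30)) {
    for (i in 1:5) {
      sim <- en$q_mean[en$opinion == i & abs(en$time - tt) < 1e-9]
      expect_lt(abs(sim - mf_at(tt, i)), 0.03)
    }
  }
})
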