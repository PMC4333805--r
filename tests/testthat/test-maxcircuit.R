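# The recurrent MAX microcircuit: algebraic fixed point and dendritic
# dynamics must agree with each other and with the brute-force
# per-supported-component maximum.

test_that("fixed point reproduces the worked examples", {
  # fully connected triad converges to the strongest feedforward drive
  tri <- max_network(c(0.2, 0.9, 0.5), rbind(c(1, 2), c(1, 3), c(2, 3)))
  expect_equal(relax_fixed_point(tri)$activity, rep(0.9, 3))

  # a single node with no recurrence holds its input
  expect_equal(relax_fixed_point(max_network(0.7))$activity, 0.7)

  # two disconnected pairs each converge to their own maximum
  pairs <- max_network(c(0.1, 0.4, 0.8, 0.2), rbind(c(1, 2), c(3, 4)))
  expect_equal(relax_fixed_point(pairs)$activity, c(0.4, 0.4, 0.8, 0.8))

  # path graph relays the maximum along the chain
  path <- max_network(c(0.3, 0.0, 0.8), rbind(c(1, 2), c(2, 3)))
  expect_equal(relax_fixed_point(path)$activity, rep(0.8, 3))

  # an unsupported node keeps its input and does not relay
  blocked <- max_network(c(0.3, 0.9, 0.8), rbind(c(1, 2), c(2, 3)),
                         support = c(TRUE, FALSE, TRUE))
  expect_equal(relax_fixed_point(blocked)$activity, c(0.3, 0.9, 0.8))

  # empty adjacency is the identity
  lone <- max_network(c(0.5, 0.1))
  expect_equal(relax_fixed_point(lone)$activity, c(0.5, 0.1))
})

test_that("dynamics converge to the same fixed point", {
  tri <- max_network(c(0.2, 0.9, 0.5), rbind(c(1, 2), c(1, 3), c(2, 3)))
  st <- relax_dynamics(tri)
  expect_true(st$converged)
  expect_equal(st$activity, rep(0.9, 3), tolerance = 1e-6)

  expect_equal(relax_dynamics(max_network(0.7))$activity, 0.7,
               tolerance = 1e-9)

  # non-convergence within t_max is reported with the residual
  big <- max_network(c(0, 1), rbind(c(1, 2)))
  expect_warning(st2 <- relax_dynamics(big, dt = 0.1, t_max = 0.3),
                 "did not converge")
  expect_false(st2$converged)
  expect_gt(st2$residual, 0)
})

test_that("fixed point equals the component-max oracle on random graphs", {
  set.seed(11)
  for (i in 1:120) {
    net <- random_net()
    want <- oracle_component_max(net$feedforward, net$edges, net$support)
    st <- relax_fixed_point(net)
    expect_true(st$converged)
    expect_equal(st$activity, want, tolerance = 1e-12)
    # asymmetry of facilitation: activity never drops below feedforward
    expect_true(all(st$activity >= net$feedforward - 1e-12))
  }
})

test_that("dynamics agree with the oracle on random graphs", {
  set.seed(12)
  for (i in 1:25) {
    net <- random_net(n_max = 20)
    want <- oracle_component_max(net$feedforward, net$edges, net$support)
    st <- relax_dynamics(net, dt = 0.1, t_max = 400, tol = 1e-10)
    expect_equal(st$activity, want, tolerance = 1e-6)
  }
})

test_that("monotonicity and idempotence hold", {
  set.seed(13)
  for (i in 1:20) {
    net <- random_net(n_max = 25)
    base <- relax_fixed_point(net)$activity
    j <- sample(net$n_nodes, 1)
    ff2 <- net$feedforward
    ff2[j] <- ff2[j] + stats::runif(1)
    bumped <- relax_fixed_point(
      max_network(ff2, net$edges, net$support, symmetric = FALSE))$activity
    expect_true(all(bumped >= base - 1e-12))
    # relaxing an already-relaxed state changes nothing: feed the fixed
    # point back as feedforward of supported nodes
    again <- relax_fixed_point(
      max_network(pmax(net$feedforward, base * net$support),
                  net$edges, net$support, symmetric = FALSE))$activity
    expect_equal(again, base, tolerance = 1e-12)
  }
})
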