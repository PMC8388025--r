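# Boolean regulatory networks and their metabolic integration.

toy <- toy_model()
net <- toy_regulatory()

test_that("synchronous updates follow rule logic and freezing", {
  st <- regulatory_state(net, c(env_s1 = TRUE))
  nxt <- synchronous_update(net, st)
  expect_true(nxt[["t1"]])
  nxt2 <- synchronous_update(net, nxt)
  expect_false(nxt2[["g2"]])          # NOT t1 with t1 on
  # frozen ids are not updated
  st2 <- regulatory_state(net, c(env_s1 = TRUE, t1 = FALSE))
  nxt3 <- synchronous_update(net, st2, frozen = "t1")
  expect_false(nxt3[["t1"]])
  # constant rules reach their value regardless of state
  cnet <- regulatory_network(c(a = "true", b = "true"))
  st3 <- regulatory_state(cnet, c(a = FALSE, b = FALSE))
  expect_true(all(synchronous_update(cnet, st3)[c("a", "b")]))
})

test_that("steady state reaches fixed points and collapses cycles", {
  ss <- regulatory_steady_state(net, regulatory_state(net, c(env_s1 = TRUE)))
  expect_true(ss$converged)
  expect_true(ss$state[["t1"]])
  expect_false(ss$state[["g2"]])
  # two-gene oscillator: conservative AND-collapse
  osc <- regulatory_network(c(a = "not b", b = "not a"))
  r <- regulatory_steady_state(osc, regulatory_state(osc,
                                                     c(a = TRUE, b = TRUE)))
  expect_false(r$converged)
  expect_false(r$state[["a"]])
  expect_false(r$state[["b"]])
  # empty network: identity, converged
  empty <- regulatory_network(character())
  r2 <- regulatory_steady_state(empty, stats::setNames(logical(), character()))
  expect_true(r2$converged)
})

test_that("rFBA couples the steady state to growth", {
  on <- rfba(toy, net, signals = c(env_s1 = TRUE))
  expect_equal(on$objective, 0.0, tolerance = 1e-9)   # R2 off, no C
  expect_identical(on$off_genes, "g2")
  off <- rfba(toy, net, signals = c(env_s1 = FALSE))
  expect_equal(off$objective, 5.0, tolerance = 1e-9)
  # TF deletion rescues growth under the repressing signal
  resc <- rfba(toy, net, frozen = "t1", signals = c(env_s1 = TRUE))
  expect_equal(resc$objective, 5.0, tolerance = 1e-9)
})

test_that("srFBA agrees with rFBA on acyclic scenarios", {
  cases <- list(list(frozen = character(), signals = c(env_s1 = TRUE)),
                list(frozen = character(), signals = c(env_s1 = FALSE)),
                list(frozen = "t1", signals = c(env_s1 = TRUE)))
  for (cs in cases) {
    a <- rfba(toy, net, frozen = cs$frozen, signals = cs$signals)
    b <- srfba(toy, net, frozen = cs$frozen, signals = cs$signals)
    expect_identical(b$status, "optimal")
    expect_equal(b$objective, a$objective, tolerance = 1e-6)
  }
  # no rules: srFBA reduces to FBA
  empty <- regulatory_network(character())
  expect_equal(srfba(toy, empty)$objective, fba(toy)$objective,
               tolerance = 1e-6)
})

test_that("linearized Boolean rules agree with direct evaluation", {
  # gate g2 (hence R2, hence growth) by expressions over up to 4 signals
  # and check every signal assignment: the MILP's gene binary must equal
  # the direct Boolean evaluation
  rules <- c("env_a and env_b",
             "env_a or (env_b and not env_c)",
             "(env_a or env_b) and (env_c or env_d)")
  for (rule in rules) {
    rn <- regulatory_network(c(g2 = rule))
    expr <- rn$rules[["g2"]]
    inputs <- strainopt:::bool_rule_vars(expr)
    for (mask in 0:(2^length(inputs) - 1)) {
      vals <- as.logical(bitwAnd(mask, 2^(seq_along(inputs) - 1)) > 0)
      direct <- strainopt:::eval_bool_rule(
        expr, stats::setNames(as.list(vals), inputs))
      r <- srfba(toy, rn, signals = stats::setNames(vals, inputs))
      expect_identical(r$regulatory_state[["g2"]], direct,
                       info = paste(rule, mask))
      expect_equal(r$objective, if (direct) 5.0 else 0.0,
                   tolerance = 1e-6, label = paste(rule, mask))
    }
  }
  # and the fixture network's state comes back from the MILP
  on <- srfba(toy, net, signals = c(env_s1 = TRUE))
  expect_true(on$regulatory_state[["t1"]])
  expect_false(on$regulatory_state[["g2"]])
  off <- srfba(toy, net, signals = c(env_s1 = FALSE))
  expect_false(off$regulatory_state[["t1"]])
  expect_true(off$regulatory_state[["g2"]])
})

test_that("rule files parse, round-trip and reject malformed lines", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  write_regulatory_rules(net, tmp)
  net2 <- read_regulatory_rules(tmp)
  expect_identical(sort(net2$targets), sort(net$targets))
  expect_identical(net2$signals, net$signals)
  r <- rfba(toy, net2, signals = c(env_s1 = TRUE))
  expect_equal(r$objective, 0.0, tolerance = 1e-9)
  writeLines("t1 not well formed", tmp)
  expect_error(read_regulatory_rules(tmp), "malformed")
})
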