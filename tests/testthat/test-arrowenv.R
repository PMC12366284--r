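# Arrow-environment extraction, canonicalization and SMARTS serialization.

test_that("shell_atoms follows bond-path distance", {
  chain <- site_state(data.frame(atom_id = 1:5, element = 6),
                      data.frame(a = 1:4, b = 2:5, order = "single"))
  expect_identical(shell_atoms(chain, 3, 1), c(2L, 3L, 4L))
  expect_identical(shell_atoms(chain, 3, 0), 3L)
  expect_identical(shell_atoms(chain, c(1, 5), 1), c(1L, 2L, 4L, 5L))
  expect_error(shell_atoms(chain, 9, 1), "unknown centre")
})

test_that("shell_atoms agrees with the brute-force BFS oracle", {
  pool <- random_arrow_pool(6, seed_base = 400L)
  for (p in pool[seq_len(min(12, length(pool)))]) {
    centres <- reaction_centres(p$arrow)
    for (depth in 0:3) {
      expect_identical(shell_atoms(p$step$state, centres, depth),
                       bf_shell(p$step$state, centres, depth))
    }
  }
})

test_that("extraction collects shells, roles and outer-shell equivalence", {
  # proton-transfer toy: H-O tail bond, tip at acceptor O
  st <- site_state(
    data.frame(atom_id = 1:5, element = c(8, 1, 8, 6, 6)),
    data.frame(a = c(1, 1, 3), b = c(2, 4, 5), order = "single"))
  arrow <- curly_arrow(2, arrow_bond(1, 2), arrow_atom(3))
  step <- catalytic_step(1, st, list(arrow))
  env <- extract_arrow_env(step, arrow, "one_away")
  # one shell: O(tail), H(tail), acceptor O(tip) + donor's C neighbour +
  # acceptor's C neighbour
  expect_setequal(env$atoms$atom_id, 1:5)
  maps <- env$atoms$map[match(1:3, env$atoms$atom_id)]
  expect_identical(maps, c("21", "21", "22"))
  # mapped atoms are exactly the reaction centres
  expect_setequal(env$atoms$atom_id[!is.na(env$atoms$map)],
                  reaction_centres(arrow))

  # two-away env is a superset of the one-away env for every fixture arrow
  s <- make_fig1_step()
  for (a in s$arrows) {
    e1 <- extract_arrow_env(s, a, "one_away")
    e2 <- extract_arrow_env(s, a, "two_away")
    expect_true(all(e1$atoms$atom_id %in% e2$atoms$atom_id))
  }

  # EzMechanism-like merges C and H at exactly the outer shell
  ez <- extract_arrow_env(s, s$arrows[[1]], "ezmechanism_like")
  tw <- extract_arrow_env(s, s$arrows[[1]], "two_away")
  expect_setequal(ez$atoms$atom_id, tw$atoms$atom_id)
  merged <- ez$atoms$atom_id[!is.na(ez$atoms$equiv)]
  expect_true(length(merged) > 0L)
  dist2 <- shell_atoms(s$state, reaction_centres(s$arrows[[1]]), 2)
  dist1 <- shell_atoms(s$state, reaction_centres(s$arrows[[1]]), 1)
  expect_true(all(merged %in% setdiff(dist2, dist1)))
  expect_true(all(ez$atoms$element[!is.na(ez$atoms$equiv)] %in% c(1L, 6L)))
})

test_that("canonical keys are invariant to atom relabelling", {
  s <- make_fig1_step()
  set.seed(42)
  for (rep in 1:5) {
    sp <- permute_step_atoms(s)
    for (def in definition_names()) {
      k1 <- vapply(arrow_envs(s, def), canonical_key, character(1))
      k2 <- vapply(arrow_envs(sp, def), canonical_key, character(1))
      expect_identical(k1, k2)
    }
  }
})

test_that("canonical keys separate label changes", {
  s <- make_fig1_step()
  e <- extract_arrow_env(s, s$arrows[[1]], "two_away")
  s2 <- s
  i <- match(14L, s2$state$atoms$atom_id)  # carboxylate carbon
  s2$state$atoms$charge[i] <- 1L
  e2 <- extract_arrow_env(s2, s2$arrows[[1]], "two_away")
  expect_false(canonical_key(e) == canonical_key(e2))
})

test_that("key equality matches VF2 isomorphism on random env pairs", {
  pool <- random_arrow_pool(8, seed_base = 500L,
                            config_args = list(atoms_per_state = c(5L, 9L)))
  envs <- lapply(pool, function(p) {
    extract_arrow_env(p$step, p$arrow, "two_away")
  })
  set.seed(7)
  for (rep in 1:40) {
    i <- sample.int(length(envs), 1L); j <- sample.int(length(envs), 1L)
    expect_identical(canonical_key(envs[[i]]) == canonical_key(envs[[j]]),
                     vf2_isomorphic(envs[[i]], envs[[j]]))
  }
  # constructed-isomorphic pairs must collide
  for (p in pool[seq_len(min(10, length(pool)))]) {
    sp <- permute_step_atoms(p$step)
    ai <- which(vapply(p$step$arrows, identical, logical(1), y = p$arrow))[1]
    ep <- extract_arrow_env(sp, sp$arrows[[ai]], "two_away")
    eo <- extract_arrow_env(p$step, p$arrow, "two_away")
    expect_identical(canonical_key(eo), canonical_key(ep))
    expect_true(vf2_isomorphic(eo, ep))
  }
})

test_that("SMARTS writer emits the reference dialect", {
  s <- make_fig1_step()
  env <- extract_arrow_env(s, s$arrows[[1]], "one_away")
  expect_identical(to_smarts(env), fig1_smarts)
  # two-electron tail-only atom carries map :21
  env3 <- extract_arrow_env(s, s$arrows[[3]], "one_away")
  at <- env3$atoms
  expect_identical(at$map[at$atom_id == 8], "21")
  expect_match(to_smarts(env3), ":21")
})

test_that("SMARTS round-trips preserve canonical keys", {
  # the reference string itself
  env <- parse_smarts_env(fig1_smarts, "one_away")
  expect_identical(nrow(env$atoms), 7L)
  expect_identical(length(strsplit(env$smarts, ".", fixed = TRUE)[[1]]), 2L)
  expect_setequal(env$atoms$map[!is.na(env$atoms$map)], c("23", "22"))
  expect_identical(to_smarts(env), fig1_smarts)

  # :23 decodes to two electrons, role both
  e23 <- parse_smarts_env("[#8:23]-[#6]", "one_away")
  expect_identical(e23$atoms$map[e23$atoms$element == 8], "23")

  # random envs, including ring-containing ones
  pool <- random_arrow_pool(6, seed_base = 600L,
                            config_args = list(extra_bond_prob = 0.15))
  for (p in pool) {
    for (def in definition_names()) {
      e <- extract_arrow_env(p$step, p$arrow, def)
      rt <- parse_smarts_env(to_smarts(e), def)
      expect_identical(canonical_key(rt), canonical_key(e))
    }
  }
})

test_that("out-of-dialect SMARTS is rejected", {
  expect_error(parse_smarts_env("CCO"), "out-of-dialect")
  expect_error(parse_smarts_env("[C]"), "out-of-dialect")
  expect_error(parse_smarts_env("[#6:99]"), "atom map")
  expect_error(parse_smarts_env("[#6](-[#8]"), "parenthes")
})

test_that("two-away key equality implies one-away and EzMechanism-like", {
  pool <- random_arrow_pool(10, seed_base = 700L)
  # add relabelled copies so the pool is guaranteed to contain colliding
  # two-away pairs and the implication check has teeth
  set.seed(19)
  for (p in pool[1:5]) {
    sp <- permute_step_atoms(p$step)
    ai <- which(vapply(p$step$arrows, identical, logical(1), y = p$arrow))[1]
    pool[[length(pool) + 1L]] <- list(step = sp, arrow = sp$arrows[[ai]])
  }
  keys <- lapply(pool, function(p) {
    vapply(definition_names(), function(def) {
      canonical_key(extract_arrow_env(p$step, p$arrow, def))
    }, character(1))
  })
  n <- length(keys)
  checked <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      if (keys[[i]]["two_away"] == keys[[j]]["two_away"]) {
        checked <- checked + 1L
        expect_identical(keys[[i]]["one_away"], keys[[j]]["one_away"])
        expect_identical(keys[[i]]["ezmechanism_like"],
                         keys[[j]]["ezmechanism_like"])
      }
    }
  }
  # the pool is seeded, so some colliding pairs exist and the test has teeth
  expect_gt(checked, 0L)
})

test_that("EzMechanism-like yields at most as many distinct envs as two-away", {
  mechs <- lapply(1:6, function(k) {
    random_mechanism(generator_config(seed = 800L + k))
  })
  ez <- length(unique(unlist(lapply(mechs, mechanism_envs,
                                    definition = "ezmechanism_like"))))
  tw <- length(unique(unlist(lapply(mechs, mechanism_envs,
                                    definition = "two_away"))))
  expect_lte(ez, tw)
})
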