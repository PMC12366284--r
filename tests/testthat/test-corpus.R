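# Corpus driver: all-vs-all tables, usage statistics, EC/CATH breakdown,
# threshold clustering.

toy_corpus <- function(n = 6L, seed_base = 2000L) {
  lapply(seq_len(n), function(k) {
    random_mechanism(generator_config(seed = seed_base + k,
                                      atoms_per_state = c(5L, 8L)))
  })
}

test_that("all_vs_all produces one deterministic row per unordered pair", {
  mechs <- toy_corpus(6)
  tab <- all_vs_all(mechs, "two_away", "unordered")
  expect_identical(nrow(tab), 15L)
  expect_true(all(tab$mech_a < tab$mech_b))
  expect_identical(tab, all_vs_all(rev(mechs), "two_away", "unordered"))

  # rows equal independent score calls
  set.seed(5)
  ids <- vapply(mechs, function(m) m$mechanism_id, character(1))
  for (r in sample(nrow(tab), 4)) {
    a <- mechs[[match(tab$mech_a[r], ids)]]
    b <- mechs[[match(tab$mech_b[r], ids)]]
    expect_identical(tab$score[r],
                     similarity_unordered(a, b, "two_away")$value)
  }

  # a duplicated mechanism under two ids scores 1.0
  dup <- mechs[[1]]; dup$mechanism_id <- "zz-duplicate"
  tab2 <- all_vs_all(c(mechs, list(dup)), "two_away", "unordered")
  row <- tab2[tab2$mech_a == mechs[[1]]$mechanism_id &
                tab2$mech_b == "zz-duplicate", ]
  expect_identical(row$score, 1)

  expect_error(all_vs_all(c(mechs, mechs[1]), "two_away"), "duplicate")
  expect_error(all_vs_all(mechs[1], "two_away"), "at least two")
})

test_that("ordered all_vs_all matches similarity_ordered", {
  mechs <- toy_corpus(4)
  tab <- all_vs_all(mechs, "one_away", "ordered")
  expect_identical(nrow(tab), 6L)
  ids <- vapply(mechs, function(m) m$mechanism_id, character(1))
  for (r in seq_len(nrow(tab))) {
    a <- mechs[[match(tab$mech_a[r], ids)]]
    b <- mechs[[match(tab$mech_b[r], ids)]]
    expect_identical(tab$score[r], similarity_ordered(a, b, "one_away")$value)
  }
})

test_that("usage statistics count envs, steps and mechanisms", {
  # corpus where every arrow is unique: all envs singletons
  stA <- site_state(data.frame(atom_id = 1:3, element = c(8, 6, 7)),
                    data.frame(a = c(1, 2), b = c(2, 3), order = "single"))
  stB <- site_state(data.frame(atom_id = 1:3, element = c(16, 6, 7)),
                    data.frame(a = c(1, 2), b = c(2, 3), order = "single"))
  mA <- mechanism("A", list(catalytic_step(1, stA, list(
    curly_arrow(2, arrow_atom(1), arrow_atom(3))))))
  mB <- mechanism("B", list(catalytic_step(1, stB, list(
    curly_arrow(2, arrow_atom(1), arrow_atom(3))))))
  st <- env_usage_stats(list(mA, mB), "two_away")
  expect_identical(st$n_arrows, 2L)
  expect_identical(st$n_distinct_envs, 2L)
  expect_identical(st$n_singleton_envs, 2L)

  # two identical mechanisms under different ids: no singletons
  mB2 <- mA; mB2$mechanism_id <- "B"
  st2 <- env_usage_stats(list(mA, mB2), "two_away")
  expect_identical(st2$n_distinct_envs, 1L)
  expect_identical(st2$n_singleton_envs, 0L)

  # totals: arrow counts over the catalogue sum to n_arrows
  mechs <- toy_corpus(5)
  st3 <- env_usage_stats(mechs, "one_away")
  expect_identical(sum(st3$catalogue$n_arrows), st3$n_arrows)
  expect_identical(st3$n_distinct_envs, nrow(st3$catalogue))
  expect_lte(st3$n_distinct_envs, st3$n_arrows)
  expect_identical(st3$n_singleton_envs +
                     sum(st3$catalogue$n_mechanisms > 1L),
                   st3$n_distinct_envs)

  # a proton-transfer env planted in 21 steps is reported as common
  proton <- function(idx) {
    stp <- site_state(data.frame(atom_id = 1:3,
                                 element = c(8, 1, 8),
                                 charge = c(0, 0, -1)),
                      data.frame(a = 1, b = 2, order = "single"))
    catalytic_step(idx, stp, list(
      curly_arrow(2, arrow_atom(3), arrow_atom(2))))
  }
  planted <- lapply(1:21, function(k) {
    mechanism(sprintf("planted-%02d", k), list(proton(1)))
  })
  st4 <- env_usage_stats(planted, "two_away", common_threshold = 20L)
  expect_identical(st4$n_common_envs, 1L)
  expect_identical(st4$catalogue$n_steps[1], 21L)

  # catalogue TSV export
  path <- tempfile(fileext = ".tsv")
  write_env_catalogue(st4, path)
  expect_identical(nrow(read.delim(path)), st4$n_distinct_envs)
})

test_that("EC/CATH breakdown classifies and conserves totals", {
  scores <- data.frame(
    mech_a = c("A", "A", "A", "B", "B", "C"),
    mech_b = c("B", "C", "D", "C", "D", "D"),
    score = c(0.9, 0.8, 0.7, 0.6, 0.55, 0.2))
  ann <- data.frame(
    mechanism_id = c("A", "B", "C", "D"),
    ec = c("3.4.21.4", "3.4.21.26", "1.1.1.1", "3.4.-.-"),
    cath = c("2.40.10.10", "2.40.10.10", "3.20.20.80",
             "2.40.10.10;3.20.20.80"))
  expect_warning(bd <- ec_cath_breakdown(scores, ann, cutoffs = 0.5),
                 "skipped")
  # A-B: same CATH set, same EC subsubclass (3.4.21)
  expect_identical(bd$same_cath_same_ec, 1L)
  # A-C and B-C: disjoint CATH, different subsubclass
  expect_identical(bd$diff_cath_diff_ec, 2L)
  # A-D and B-D: partial CATH overlap, kept separate; D's EC is wildcarded
  # at the third level so those pairs count as unannotated instead
  expect_identical(bd$cath_partial, 0L)
  expect_identical(bd$unannotated, 2L)
  expect_identical(bd$n_pairs, 5L)
  # conservation: the four cells + partial + unannotated = pairs above cutoff
  expect_identical(bd$same_cath_same_ec + bd$same_cath_diff_ec +
                     bd$diff_cath_same_ec + bd$diff_cath_diff_ec +
                     bd$cath_partial + bd$unannotated,
                   bd$n_pairs)

  # with a complete EC on D the partial-overlap category fills instead
  ann$ec[4] <- "3.4.21.7"
  bd2 <- ec_cath_breakdown(scores, ann, cutoffs = c(0.5, 0.75))
  expect_identical(bd2$cath_partial, c(2L, 0L))
  expect_identical(bd2$unannotated, c(0L, 0L))
  expect_identical(bd2$n_pairs, c(5L, 2L))
  # pairs above a higher cutoff are a subset of those above a lower one
  expect_true(all(bd2$n_pairs[2] <= bd2$n_pairs[1]))
})

test_that("threshold clustering returns components plus isolates", {
  scores <- data.frame(mech_a = c("A", "A", "B"),
                       mech_b = c("B", "C", "C"),
                       score = c(0.6, 0.1, 0.2))
  cl <- cluster_graph(scores, 0.5)
  expect_identical(cl$components, list(c("A", "B")))
  expect_identical(cl$isolated, "C")
  # cutoff above every score: everything isolated
  cl2 <- cluster_graph(scores, 0.95)
  expect_length(cl2$components, 0L)
  expect_identical(cl2$isolated, c("A", "B", "C"))
  # conservation of members
  n <- sum(lengths(cl$components)) + length(cl$isolated)
  expect_identical(n, 3L)
})
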