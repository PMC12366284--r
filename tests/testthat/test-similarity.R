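# Unordered and ordered similarity at step and mechanism level.

test_that("jaccard follows the set formula with the empty-set convention", {
  expect_identical(jaccard(1:4, 3:6), 2 / 6)
  # four shared elements over a union of eight
  expect_identical(jaccard(letters[1:6], letters[3:8]), 0.5)
  expect_identical(jaccard(letters[1:3], letters[1:3]), 1)
  expect_identical(jaccard(1:2, 3:4), 0)
  expect_identical(jaccard(character(0), character(0)), 1)
  expect_identical(jaccard(c(1, 1, 2), c(2, 2, 1)), 1)  # set semantics
})

test_that("mechanism env sets pool distinct keys across steps", {
  p <- make_glycosidase_pair()
  expect_length(mechanism_envs(p$amylase, "two_away"), 6L)
  expect_length(mechanism_envs(p$xet, "two_away"), 6L)

  # a mechanism with one single-arrow step has a singleton env set
  st <- site_state(data.frame(atom_id = 1:2, element = c(8, 1)),
                   data.frame(a = 1, b = 2, order = "single"))
  m1 <- mechanism("tiny", list(catalytic_step(1, st, list(
    curly_arrow(2, arrow_atom(1), arrow_atom(2))))))
  expect_length(mechanism_envs(m1, "two_away"), 1L)

  # an env duplicated across steps counts once
  m2 <- mechanism("dup", list(
    catalytic_step(1, st, list(curly_arrow(2, arrow_atom(1), arrow_atom(2)))),
    catalytic_step(2, st, list(curly_arrow(2, arrow_atom(1), arrow_atom(2))))))
  expect_length(mechanism_envs(m2, "two_away"), 1L)
})

test_that("the worked example scores 50% unordered and 42% ordered", {
  p <- make_glycosidase_pair()
  su <- similarity_unordered(p$amylase, p$xet, "two_away")
  expect_identical(su$value, 0.5)
  expect_identical(format_percent(su$value), "50%")
  so <- similarity_ordered(p$amylase, p$xet, "two_away")
  expect_equal(so$value, mean(c(4 / 8, 2 / 6)), tolerance = 1e-12)
  expect_identical(format_percent(so$value), "42%")
  expect_identical(so$j_envs, 0.5)
  expect_equal(so$j_chains, 2 / 6, tolerance = 1e-12)
  # ordered < unordered here, as the chain overlap is weaker
  expect_lt(so$value, su$value)

  # first steps are identical, so step-level unordered similarity is 1
  s1 <- similarity_unordered(p$amylase$steps[[1]], p$xet$steps[[1]],
                             "two_away")
  expect_identical(s1$value, 1)
})

test_that("score_suite covers all six combinations consistently", {
  p <- make_glycosidase_pair()
  tab <- score_suite(p$amylase, p$xet)
  expect_identical(nrow(tab), 6L)
  expect_setequal(tab$definition, definition_names())
  for (r in seq_len(nrow(tab))) {
    f <- if (tab$method[r] == "unordered") similarity_unordered else
      similarity_ordered
    expect_identical(tab$score[r],
                     f(p$amylase, p$xet, tab$definition[r])$value)
  }
  row <- tab[tab$definition == "two_away" & tab$method == "ordered", ]
  expect_identical(row$percent, "42%")

  # identical mechanisms: all six scores are 1
  self <- score_suite(p$amylase, p$amylase)
  expect_true(all(self$score == 1))
})

test_that("fully disjoint chemistry scores zero everywhere", {
  # element-translate one mechanism wholesale (C->N, O->S, H->F): every env
  # and every chain label changes, so nothing can match
  p <- make_glycosidase_pair()
  mA <- p$amylase
  mB <- p$amylase
  mB$mechanism_id <- "translated"
  for (si in seq_along(mB$steps)) {
    el <- mB$steps[[si]]$state$atoms$element
    mB$steps[[si]]$state$atoms$element <-
      ifelse(el == 6L, 7L, ifelse(el == 8L, 16L, ifelse(el == 1L, 9L, el)))
  }
  expect_identical(validate_mechanism(mB), character(0))
  tab <- score_suite(mA, mB)
  expect_true(all(tab$score == 0))
})

test_that("chain-free mechanisms rely on the empty-chain convention", {
  st <- site_state(data.frame(atom_id = 1:2, element = c(8, 1)),
                   data.frame(a = 1, b = 2, order = "single"))
  mk <- function(id) mechanism(id, list(catalytic_step(1, st, list(
    curly_arrow(2, arrow_atom(1), arrow_atom(2))))))
  so <- similarity_ordered(mk("a"), mk("b"), "two_away")
  expect_identical(so$value, 1)
  expect_identical(so$j_chains, 1)
})

test_that("levels and definitions cannot be mixed", {
  p <- make_glycosidase_pair()
  expect_error(similarity_unordered(p$amylase, p$xet$steps[[1]]),
               "cannot compare")
})

test_that("scores are symmetric, reflexive and in range on random pairs", {
  mechs <- lapply(1:8, function(k) {
    random_mechanism(generator_config(seed = 1000L + k,
                                      atoms_per_state = c(5L, 9L)))
  })
  set.seed(3)
  for (rep in 1:10) {
    ij <- sample.int(length(mechs), 2L)
    a <- mechs[[ij[1]]]; b <- mechs[[ij[2]]]
    for (def in definition_names()) {
      su_ab <- similarity_unordered(a, b, def)$value
      su_ba <- similarity_unordered(b, a, def)$value
      so_ab <- similarity_ordered(a, b, def)$value
      so_ba <- similarity_ordered(b, a, def)$value
      expect_identical(su_ab, su_ba)
      expect_identical(so_ab, so_ba)
      expect_true(su_ab >= 0 && su_ab <= 1)
      expect_true(so_ab >= 0 && so_ab <= 1)
      expect_identical(similarity_unordered(a, a, def)$value, 1)
      expect_identical(similarity_ordered(a, a, def)$value, 1)
    }
  }
})

test_that("display rounding is half-up to integer percent", {
  expect_identical(format_percent(0.41667), "42%")
  expect_identical(format_percent(0.5), "50%")
  expect_identical(format_percent(0.125), "13%")
  expect_identical(format_percent(c(0, 1)), c("0%", "100%"))
})
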