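four_point_set <- function() {
  fundamental_set(rbind(c(1, 1), c(3, 1), c(-1, -1), c(-3, -1)),
                  c(0, 0, 1, 1))
}

test_that("one-hot codes are Kronecker deltas and stack to the identity", {
  expect_identical(encode_one_hot(2, 3), c(0L, 1L, 0L))
  expect_identical(encode_one_hot(1, 1), 1L)
  expect_equal(t(sapply(1:5, encode_one_hot, p = 5)), diag(5))
  expect_error(encode_one_hot(4, 3), "out of range")
})

test_that("masking vectors indicate class membership and partition the patterns", {
  masks <- build_masking_vectors(c(1, 2, 1, 2), 2)
  expect_identical(masks[1, ], c(1L, 0L, 1L, 0L))
  expect_identical(masks[2, ], c(0L, 1L, 0L, 1L))
  expect_identical(build_masking_vectors(rep(1, 4), 1)[1, ], rep(1L, 4))
  set.seed(2)
  lab <- sample(1:4, 30, replace = TRUE)
  expect_identical(colSums(build_masking_vectors(lab, 4)), rep(1, 30))
  expect_error(build_masking_vectors(c(1, 5), 4), "out of range")
})

test_that("CHAT-OHM learning stacks translated patterns and equals outer-product accumulation", {
  fit <- chat_ohm_fit(four_point_set())
  expect_equal(fit$weights, rbind(c(1, 1), c(3, 1), c(-1, -1), c(-3, -1)))
  expect_identical(fit$masks, rbind(c(1L, 1L, 0L, 0L), c(0L, 0L, 1L, 1L)))

  # literal Linear-Associator learning with per-pattern one-hot outputs
  fs <- random_blob_set(31, counts = c(8, 11))
  f <- chat_ohm_fit(fs)
  Xhat <- sweep(fs$X, 2, colMeans(fs$X))
  Y <- t(sapply(seq_len(nrow(Xhat)), encode_one_hot, p = nrow(Xhat)))
  expect_equal(f$weights, oracle_linear_associator(Xhat, Y))

  single <- chat_ohm_fit(fundamental_set(rbind(c(2, 5)), 1))
  expect_equal(single$weights, rbind(c(0, 0)))
})

test_that("recovery flags the arg-max set of pattern scores", {
  fit <- chat_ohm_fit(four_point_set())
  expect_identical(chat_ohm_recover(fit, c(2, 1)), c(0L, 1L, 0L, 0L))
  # query at the centroid: every score zero, total tie
  expect_identical(chat_ohm_recover(fit, c(0, 0)), rep(1L, 4))
  tie <- make_tie_fixture()
  tfit <- chat_ohm_fit(tie$data)
  expect_identical(chat_ohm_recover(tfit, tie$query), c(1L, 1L))
  expect_error(chat_ohm_recover(fit, c(1, 2, 3)), "length 3")
})

test_that("vote counting ANDs the recovered vector with each mask", {
  masks <- build_masking_vectors(c(1, 2, 1, 2), 2)
  expect_identical(count_votes(c(1, 0, 1, 1), masks), c(2L, 1L))
  expect_identical(count_votes(rep(1, 4), masks), c(2L, 2L))
  set.seed(8)
  for (i in 1:10) {
    rec <- sample(0:1, 4, replace = TRUE)
    naive <- c(sum(rec & masks[1, ]), sum(rec & masks[2, ]))
    expect_identical(count_votes(rec, masks), as.integer(naive))
    # conservation: votes sum to the number of recovered patterns
    expect_identical(sum(count_votes(rec, masks)), sum(rec))
  }
  expect_error(count_votes(c(1, 0), masks), "length 2")
})

test_that("CHAT-OHM prediction majority-votes with smallest-index tie rule", {
  fit <- chat_ohm_fit(four_point_set())
  expect_identical(chat_ohm_predict(fit, c(2, 1)), "0")
  tie <- make_tie_fixture()
  tfit <- chat_ohm_fit(tie$data)
  expect_identical(chat_ohm_predict(tfit, tie$query), tie$data$label_map[1])
})

test_that("CHAT-OHM equals the centered-inner-product nearest-pattern oracle", {
  set.seed(55)
  for (d in 1:10) {
    fs <- random_blob_set(1000 + d, sep = 5, counts = c(30, 30), n = 2)
    fit <- chat_ohm_fit(fs)
    queries <- matrix(rnorm(60, sd = 4), 30, 2)
    for (q in seq_len(nrow(queries))) {
      want <- oracle_nn_label(fs$X, fs$labels, queries[q, ])
      if (is.na(want)) next
      expect_identical(chat_ohm_predict(fit, queries[q, ]),
                       fs$label_map[want])
    }
  }
})

test_that("CHAT-OHM predictions are invariant to translation, scaling and training order", {
  for (seed in 1:5) {
    fs <- random_blob_set(seed + 40, sep = 4, counts = c(10, 14))
    fit <- chat_ohm_fit(fs)
    set.seed(seed + 200)
    queries <- matrix(rnorm(10 * ncol(fs$X), sd = 3), 10)
    base <- chat_ohm_predict(fit, queries)

    shift <- rnorm(ncol(fs$X), sd = 20)
    fit_sh <- chat_ohm_fit(fundamental_set(sweep(fs$X, 2, -shift),
                                           fs$label_map[fs$labels]))
    expect_identical(chat_ohm_predict(fit_sh, sweep(queries, 2, -shift)), base)

    a <- 0.42
    fit_sc <- chat_ohm_fit(fundamental_set(a * fs$X, fs$label_map[fs$labels]))
    expect_identical(chat_ohm_predict(fit_sc, a * queries), base)

    perm <- sample(nrow(fs$X))
    fit_pm <- chat_ohm_fit(fundamental_set(fs$X[perm, ],
                                           fs$label_map[fs$labels][perm]))
    # permuting training rows permutes weights/masks consistently
    expect_equal(fit_pm$weights, fit$weights[perm, ])
    expect_identical(fit_pm$masks, fit$masks[, perm, drop = FALSE])
    expect_identical(chat_ohm_predict(fit_pm, queries), base)
  }
})

test_that("CHAT-OHM achieves 100% training accuracy when self-similarity dominates", {
  fs <- random_blob_set(77, sep = 12, sigma = 1, counts = c(25, 25), n = 2)
  fit <- chat_ohm_fit(fs)
  expect_identical(chat_ohm_predict(fit, fs$X), fs$label_map[fs$labels])
})
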