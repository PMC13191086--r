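test_that("transcript labeling is conjunctive across all contexts", {
  ctx <- sprintf("cell%02d", 1:12)
  mk <- function(vals) {
    out <- tibble::tibble(gene_id = sprintf("g%d", seq_len(nrow(vals))))
    for (j in seq_along(ctx)) out[[ctx[j]]] <- vals[, j]
    out
  }
  eps <- 0.1
  # gene 1: log2FC exactly 1 everywhere; gene 2: +2 in 11, -2 in one;
  # gene 3: all-zero expression; gene 4: <= -1 everywhere
  cyt <- matrix(1, 4, 12)
  nuc <- matrix(0, 4, 12)
  nuc[1, ] <- 2 * (1 + eps) - eps            # ratio exactly 2
  nuc[2, ] <- 4 * (1 + eps) - eps
  nuc[2, 7] <- (1 + eps) / 4 - eps
  nuc[3, ] <- 0; cyt[3, ] <- 0
  nuc[4, ] <- (1 + eps) / 2 - eps            # ratio exactly 1/2
  labs <- label_transcripts(mk(nuc), mk(cyt), label_rule())
  expect_equal(labs$label, c("nuclear", "excluded", "excluded", "cytoplasmic"))

  expect_error(label_transcripts(mk(nuc)[, 1:10], mk(cyt), label_rule()),
               "aligned")
  expect_error(label_transcripts(mk(nuc), mk(cyt), label_rule(n_contexts = 3)),
               "contexts")
})

test_that("encoding lifts scalars over positional encodings with CLS and padding", {
  cfg <- encoder_config(m = 16, max_len = 12, mode = "nrs_raw")
  z <- encode(rep(0, 7), cfg)
  expect_equal(dim(z), c(13L, 16L))
  expect_equal(sum(attr(z, "mask")), 8L)
  # zero scores: rows are positional encoding plus bias alone
  params <- nrscreen:::nn_init(16, 1L, 1L, 16, "nrs_raw", seed = 1L)
  z2 <- encode(rep(0, 7), cfg, params)
  pe <- nrscreen:::sinusoidal_pe(7, 16)
  expect_equal(unname(z2[2:8, ]),
               unname(pe + matrix(params$b_emb, 7, 16, byrow = TRUE)))
  expect_equal(unname(z2[1, ]), params$cls)
  # different lengths pad to the same shape with different masks
  za <- encode(rep(0.5, 4), cfg, params)
  expect_equal(dim(za), dim(z2))
  expect_false(identical(attr(za, "mask"), attr(z2, "mask")))
  expect_error(encode(rep(0, 20), cfg, params), "max_len")
})

test_that("backpropagation matches finite-difference gradients", {
  m <- 8L
  for (mode in c("nrs_raw", "baseline_kmer")) {
    params <- nrscreen:::nn_init(m, 2L, 2L, 2L * m, mode, seed = 3L)
    x <- if (mode == "baseline_kmer") c(5L, 19L, 101L, 7L) else
      c(0.5, -1, 0.2, 1.4)
    y <- 1L
    fw <- nrscreen:::nn_forward(params, x, mode, 2L, keep_cache = TRUE)
    dlogit <- 1 / (1 + exp(-fw$logit)) - y
    g <- nrscreen:::nn_backward(params, x, mode, 2L, fw, dlogit)
    eps <- 1e-5
    loss_at <- function(p) {
      nrscreen:::bce_loss(nrscreen:::nn_forward(p, x, mode, 2L), y)
    }
    # central finite difference at one index of a parameter leaf
    check <- function(path_get, path_set, idx, analytic) {
      shift <- function(h) {
        p2 <- params
        v <- path_get(p2)
        v[idx] <- v[idx] + h
        path_set(p2, v)
      }
      num <- (loss_at(shift(eps)) - loss_at(shift(-eps))) / (2 * eps)
      expect_lt(abs(num - analytic), 1e-6 + 1e-3 * abs(analytic))
    }
    check(function(p) p$layers[[1]]$Wq,
          function(p, v) { p$layers[[1]]$Wq <- v; p }, 10L,
          g$layers[[1]]$Wq[10L])
    check(function(p) p$layers[[2]]$W2,
          function(p, v) { p$layers[[2]]$W2 <- v; p }, 3L,
          g$layers[[2]]$W2[3L])
    check(function(p) p$cls, function(p, v) { p$cls <- v; p }, 2L, g$cls[2L])
    check(function(p) p$w_out, function(p, v) { p$w_out <- v; p }, 1L,
          g$w_out[1L])
    if (mode == "baseline_kmer") {
      check(function(p) p$E, function(p, v) { p$E <- v; p },
            5L + (2L - 1L) * 4096L, g$E[5L, 2L])  # E[5, 2]
    } else {
      check(function(p) p$w_emb, function(p, v) { p$w_emb <- v; p }, 4L,
            g$w_emb[4L])
    }
  }
})

test_that("training recovers planted signal and is reproducible", {
  truth <- sim_kmer_truth(40, 40, 1, seed = 9)
  nuc <- truth$element[truth$class_true == "nuclear"]
  cyt <- truth$element[truth$class_true == "cytoplasmic"]
  tab <- tibble::tibble(element = truth$element, nrs = truth$log2_enrichment)
  tx <- sim_transcripts(60, 100, 160, nuc, cyt, copies_per_transcript = 10,
                        seed = 10)
  model <- train_localization_model(
    tx, tab, encoder_config(m = 16, mode = "nrs_raw"),
    train_config(epochs = 6, seed = 1))
  expect_equal(nrow(model$curves), 6L)
  expect_gte(tail(model$curves$test_accuracy, 1), 0.85)

  model2 <- train_localization_model(
    tx, tab, encoder_config(m = 16, mode = "nrs_raw"),
    train_config(epochs = 6, seed = 1))
  expect_identical(model$curves, model2$curves)

  single <- dplyr::mutate(tx, label = "nuclear")
  expect_error(
    train_localization_model(single, tab, encoder_config(m = 16),
                             train_config(epochs = 1)),
    "both classes")
})

test_that("ROC/PR areas equal the pairwise concordance oracle", {
  perfect <- roc_curve(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(attr(perfect, "auc"), 1)

  # hand-built 6-item list with a tie
  scores <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  labels <- c(1, 0, 1, 1, 0, 0)
  roc <- roc_curve(scores, labels)
  expect_equal(attr(roc, "auc"), concordance_auroc(scores, labels))
  expect_equal(attr(roc, "auc"),
               suppressMessages(as.numeric(pROC::auc(labels, scores))))

  withr::with_seed(12, {
    for (i in 1:10) {
      s <- round(runif(20), 2)
      l <- rbinom(20, 1, 0.5)
      if (length(unique(l)) < 2) next
      expect_equal(attr(roc_curve(s, l), "auc"), concordance_auroc(s, l))
    }
  })
  # label-independent scores give chance-level AUROC
  withr::with_seed(13, {
    s <- runif(400)
    l <- rbinom(400, 1, 0.5)
  })
  expect_lt(abs(attr(roc_curve(s, l), "auc") - 0.5), 0.08)
  pr <- pr_curve(c(0.9, 0.8, 0.2), c(1, 1, 0))
  expect_equal(attr(pr, "auc"), 1)
})

test_that("model evaluation, tidiers and checkpointing are consistent", {
  truth <- sim_kmer_truth(30, 30, 1, seed = 14)
  tab <- tibble::tibble(element = truth$element, nrs = truth$log2_enrichment)
  tx <- sim_transcripts(25, 80, 120,
                        truth$element[truth$class_true == "nuclear"],
                        truth$element[truth$class_true == "cytoplasmic"],
                        copies_per_transcript = 6, seed = 15)
  model <- train_localization_model(
    tx, tab, encoder_config(m = 16, mode = "nrs_raw"),
    train_config(epochs = 3, seed = 2))
  ev <- evaluate_model(model)
  expect_true(ev$auroc >= 0 && ev$auroc <= 1)
  expect_equal(nrow(tidy(model)), 3L)
  expect_equal(glance(model)$test_accuracy,
               tail(model$curves$test_accuracy, 1))
  expect_equal(glance(ev)$auroc, ev$auroc)
  expect_s3_class(tidy(ev, "roc"), "tbl_df")

  f <- withr::local_tempfile(fileext = ".json")
  save_model(model, f)
  back <- load_model(f)
  p1 <- predict(model, tx[1:5, ], tab)
  p2 <- predict(back, tx[1:5, ], tab)
  expect_equal(p1$score, p2$score, tolerance = 1e-10)
  expect_equal(back$curves$test_loss, model$curves$test_loss,
               tolerance = 1e-12)
})
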