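#' Labeling rule for fraction expression across cell contexts
#'
#' A transcript is nuclear-enriched when its nuclear:cytoplasmic log2 fold
#' change is at least `lfc_cut` in *every* context (conjunctive across the
#' 12 cell types by default), cytoplasmic-enriched when it is at most
#' `-lfc_cut` in every context, and excluded otherwise.
#'
#' @param lfc_cut Log2 fold-change threshold (inclusive; default 1).
#' @param n_contexts Expected number of cell contexts (default 12).
#' @param pseudocount FPKM pseudocount guarding zero expression
#'   (default 0.1).
#' @return A list of class `label_rule`.
#' @export
label_rule <- function(lfc_cut = 1, n_contexts = 12L, pseudocount = 0.1) {
  stopifnot(lfc_cut > 0, pseudocount >= 0)
  structure(list(lfc_cut = lfc_cut,
                 n_contexts = check_scalar_int(n_contexts, "n_contexts", 1),
                 pseudocount = pseudocount),
            class = "label_rule")
}

#' Label transcripts from nuclear/cytoplasmic FPKM matrices
#'
#' @param fpkm_nuc,fpkm_cyt Tibbles with `gene_id` plus one numeric column
#'   per cell context, aligned on genes and contexts.
#' @param rule A [label_rule()].
#' @return Tibble with `gene_id`, `label` in
#'   `{nuclear, cytoplasmic, excluded}`.
#' @export
label_transcripts <- function(fpkm_nuc, fpkm_cyt, rule = label_rule()) {
  ctx <- setdiff(names(fpkm_nuc), "gene_id")
  if (!identical(ctx, setdiff(names(fpkm_cyt), "gene_id")) ||
      !identical(fpkm_nuc$gene_id, fpkm_cyt$gene_id)) {
    abort("FPKM matrices must be aligned on genes and contexts")
  }
  if (length(ctx) != rule$n_contexts) {
    abort(sprintf("expected %d contexts, got %d", rule$n_contexts,
                  length(ctx)))
  }
  eps <- rule$pseudocount
  lfc <- log2((as.matrix(fpkm_nuc[, ctx]) + eps) /
                (as.matrix(fpkm_cyt[, ctx]) + eps))
  tibble(
    gene_id = fpkm_nuc$gene_id,
    label = dplyr::case_when(
      rowSums(lfc >= rule$lfc_cut) == length(ctx) ~ "nuclear",
      rowSums(lfc <= -rule$lfc_cut) == length(ctx) ~ "cytoplasmic",
      TRUE ~ "excluded"
    )
  )
}

#' Encoder configuration for the localization classifier
#'
#' @param m Embedding width (default 256).
#' @param max_len Longest input length accepted; `NULL` takes the longest
#'   transcript in the training set.
#' @param mode Input encoding: raw window NRS (`nrs_raw`), per-nucleotide
#'   averaged NRS (`nrs_avg`), the randomized-table controls (`rand_raw`,
#'   `rand_avg`), or a 6-mer-identity embedding with no NRS information
#'   (`baseline_kmer`).
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(m = 256L, max_len = NULL,
                           mode = c("nrs_raw", "nrs_avg", "rand_raw",
                                    "rand_avg", "baseline_kmer")) {
  m <- check_scalar_int(m, "m", min = 8)
  structure(list(m = m, max_len = max_len, mode = match.arg(mode)),
            class = "encoder_config")
}

#' Training configuration for the localization classifier
#'
#' Defaults follow the screen's training regime: a stratified 80/20
#' train/test split and training stopped after 6 epochs (the point at
#' which the test loss starts to rise at this scale).
#'
#' @param train_frac Fraction of transcripts used for training.
#' @param epochs Training epochs.
#' @param seed Integer seed for the split, initialization and shuffling.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param n_layers,n_heads Depth and heads of the attention stack.
#' @return A list of class `train_config`.
#' @export
train_config <- function(train_frac = 0.8, epochs = 6L, seed = 1L,
                         batch_size = 16L, lr = 2e-3, n_layers = 2L,
                         n_heads = 4L) {
  stopifnot(train_frac > 0, train_frac < 1)
  structure(
    list(train_frac = train_frac,
         epochs = check_scalar_int(epochs, "epochs", 1),
         seed = check_scalar_int(seed, "seed"),
         batch_size = check_scalar_int(batch_size, "batch_size", 1),
         lr = lr,
         n_layers = check_scalar_int(n_layers, "n_layers", 1),
         n_heads = check_scalar_int(n_heads, "n_heads", 1)),
    class = "train_config"
  )
}

# per-transcript model input for a mode: scalar score vector or 6-mer ids
encode_input <- function(sequence, nrs_vec, mode) {
  L <- nchar(sequence)
  win <- substring(sequence, seq_len(L - 5L), seq_len(L - 5L) + 5L)
  if (mode == "baseline_kmer") {
    idx <- match(win, kmer_universe())
    idx[is.na(idx)] <- 1L
    return(idx)
  }
  raw <- unname(nrs_vec[win])
  raw[is.na(raw)] <- 0
  if (mode %in% c("nrs_avg", "rand_avg")) window_average(raw, L) else raw
}

.kmer_universe <- NULL

kmer_universe <- function() {
  if (is.null(.kmer_universe)) {
    utils::assignInMyNamespace(".kmer_universe", all_kmers(6L))
  }
  .kmer_universe
}

#' Encode a transcript profile as an (n+1) x m feature matrix
#'
#' The scalar NRS at each position is lifted to `m` dimensions by the
#' learned linear map plus a sinusoidal positional encoding (an all-zero
#' NRS vector therefore encodes to the positional encoding plus bias
#' alone); `baseline_kmer` mode uses a learned 4096-way 6-mer embedding
#' instead of the NRS. Sequences shorter than `max_len` are padded with
#' zero rows flagged in the `mask` attribute, and the learned CLS row is
#' prepended.
#'
#' @param profile An `nrs_profile` (or numeric score vector).
#' @param cfg An [encoder_config()] with non-NULL `max_len`.
#' @param params Model parameters (e.g. from a fitted model); fresh
#'   seed-1 initialized parameters are used when omitted.
#' @return `(max_len + 1) x m` numeric matrix with attribute `mask`
#'   (length `max_len + 1`; TRUE for the CLS row and real positions).
#' @export
encode <- function(profile, cfg, params = NULL) {
  stopifnot(inherits(cfg, "encoder_config"), !is.null(cfg$max_len))
  x <- if (inherits(profile, "nrs_profile")) {
    if (cfg$mode %in% c("nrs_avg", "rand_avg")) profile$averaged else profile$raw
  } else {
    profile
  }
  T <- length(x)
  if (T > cfg$max_len) abort("input longer than max_len")
  if (is.null(params)) {
    params <- nn_init(cfg$m, n_layers = 1L, n_heads = 1L, hidden = cfg$m,
                      mode = cfg$mode, seed = 1L)
  }
  pe <- sinusoidal_pe(T, cfg$m)
  rows <- if (cfg$mode == "baseline_kmer") {
    params$E[x, , drop = FALSE] + pe
  } else {
    outer(as.numeric(x), params$w_emb) +
      matrix(params$b_emb, T, cfg$m, byrow = TRUE) + pe
  }
  out <- rbind(params$cls, rows,
               matrix(0, cfg$max_len - T, cfg$m))
  rownames(out) <- NULL
  attr(out, "mask") <- c(TRUE, rep(TRUE, T), rep(FALSE, cfg$max_len - T))
  out
}

#' Train the NRS-guided localization classifier
#'
#' Transcripts labelled nuclear or cytoplasmic are encoded per the
#' configured mode and classified by a compact multi-head self-attention
#' stack whose CLS-row representation feeds a linear head. The split is
#' stratified 80/20 under the seed; per-epoch train/test accuracy and
#' loss are recorded. The randomized-NRS control modes permute the NRS
#' table (preserving its value distribution) before encoding.
#'
#' @param transcripts Tibble with `transcript_id`, `label` (nuclear /
#'   cytoplasmic), `sequence`.
#' @param nrs_table Tibble with `element`, `nrs` covering all 6-mers.
#' @param encoder An [encoder_config()].
#' @param config A [train_config()].
#' @return Object of class `loc_model`: parameters, per-epoch `curves`,
#'   configs, split indices and cached inputs.
#' @export
train_localization_model <- function(transcripts, nrs_table,
                                     encoder = encoder_config(),
                                     config = train_config()) {
  labs <- transcripts$label
  if (!all(labs %in% c("nuclear", "cytoplasmic"))) {
    abort("labels must be 'nuclear' or 'cytoplasmic'")
  }
  if (length(unique(labs)) < 2L) abort("both classes must be present")
  tab <- if (encoder$mode %in% c("rand_raw", "rand_avg")) {
    randomize_nrs(nrs_table, seed = config$seed)
  } else {
    nrs_table
  }
  nrs_vec <- as_nrs_vector(tab)
  if (encoder$mode == "baseline_kmer") kmer_universe()
  inputs <- purrr::map(transcripts$sequence, encode_input,
                       nrs_vec = nrs_vec, mode = encoder$mode)
  y <- as.integer(labs == "nuclear")
  if (is.null(encoder$max_len)) {
    encoder$max_len <- max(nchar(transcripts$sequence))
  }
  withr::local_seed(config$seed)
  idx_train <- sort(unlist(lapply(split(seq_along(y), y), function(ii) {
    sample(ii, floor(config$train_frac * length(ii)))
  })))
  idx_test <- setdiff(seq_along(y), idx_train)
  if (length(unique(y[idx_test])) < 2L || length(unique(y[idx_train])) < 2L) {
    abort("both classes must be present in train and test splits")
  }
  params <- nn_init(encoder$m, config$n_layers, config$n_heads,
                    hidden = 2L * encoder$m, mode = encoder$mode,
                    seed = config$seed)
  opt <- adam_init(params)
  curves <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    order_ep <- sample(idx_train)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / config$batch_size))
    # train metrics are accumulated from the pre-update training passes
    # (the usual running estimate), the test set is evaluated post-epoch
    tr_correct <- 0L
    tr_loss <- 0
    for (b in batches) {
      g <- NULL
      for (i in b) {
        fw <- nn_forward(params, inputs[[i]], encoder$mode, config$n_heads,
                         keep_cache = TRUE)
        tr_correct <- tr_correct + ((fw$logit > 0) == (y[i] == 1L))
        tr_loss <- tr_loss + bce_loss(fw$logit, y[i])
        dlogit <- (1 / (1 + exp(-fw$logit)) - y[i]) / length(b)
        gi <- nn_backward(params, inputs[[i]], encoder$mode, config$n_heads,
                          fw, dlogit)
        g <- if (is.null(g)) gi else tree_map2(`+`, g, gi)
      }
      res <- adam_step(params, g, opt, lr = config$lr)
      params <- res$params
      opt <- res$state
    }
    te <- dataset_metrics(params, inputs, y, idx_test, encoder$mode,
                          config$n_heads)
    curves[[ep]] <- tibble(epoch = ep,
                           train_accuracy = tr_correct / length(idx_train),
                           test_accuracy = te$acc,
                           train_loss = tr_loss / length(idx_train),
                           test_loss = te$loss)
  }
  structure(
    list(params = params, curves = bind_rows(curves), encoder = encoder,
         config = config,
         data = list(inputs = inputs, y = y,
                     transcript_id = transcripts$transcript_id,
                     idx_train = idx_train, idx_test = idx_test)),
    class = "loc_model"
  )
}

dataset_metrics <- function(params, inputs, y, idx, mode, n_heads) {
  logits <- vapply(idx, function(i) {
    nn_forward(params, inputs[[i]], mode, n_heads)
  }, numeric(1))
  list(acc = mean((logits > 0) == (y[idx] == 1L)),
       loss = mean(bce_loss(logits, y[idx])))
}

#' @export
print.loc_model <- function(x, ...) {
  last <- tail(x$curves, 1L)
  cat(sprintf(
    "<loc_model> mode=%s m=%d layers=%d heads=%d | epoch %d: test acc %.3f\n",
    x$encoder$mode, x$encoder$m, x$config$n_layers, x$config$n_heads,
    last$epoch, last$test_accuracy))
  invisible(x)
}

#' Predict nuclear-class scores for transcripts
#'
#' @param object A fitted `loc_model`.
#' @param transcripts Tibble with `sequence` (and optionally
#'   `transcript_id`); defaults to the held-out test set.
#' @param nrs_table Table used to encode new transcripts; defaults to the
#'   training encoding cached in the model for the test set.
#' @param ... Unused.
#' @return Tibble with `transcript_id`, `score` (sigmoid of the logit),
#'   and `label` when known.
#' @export
predict.loc_model <- function(object, transcripts = NULL, nrs_table = NULL,
                              ...) {
  if (is.null(transcripts)) {
    idx <- object$data$idx_test
    logits <- vapply(idx, function(i) {
      nn_forward(object$params, object$data$inputs[[i]], object$encoder$mode,
                 object$config$n_heads)
    }, numeric(1))
    return(tibble(
      transcript_id = object$data$transcript_id[idx],
      score = 1 / (1 + exp(-logits)),
      label = c("cytoplasmic", "nuclear")[object$data$y[idx] + 1L]
    ))
  }
  if (is.null(nrs_table)) abort("nrs_table needed to encode new transcripts")
  nrs_vec <- as_nrs_vector(nrs_table)
  logits <- vapply(transcripts$sequence, function(s) {
    nn_forward(object$params,
               encode_input(s, nrs_vec, object$encoder$mode),
               object$encoder$mode, object$config$n_heads)
  }, numeric(1))
  tibble(
    transcript_id = transcripts$transcript_id %||% seq_along(logits),
    score = 1 / (1 + exp(-logits))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted localization model
#'
#' Accuracy at score 0.5 plus ROC and precision-recall curves from a
#' threshold sweep on the nuclear-class score, with trapezoidal areas.
#'
#' @param model A fitted `loc_model`.
#' @return Object of class `loc_eval`: `accuracy`, `roc` (tibble with
#'   `fpr`, `tpr`), `auroc`, `pr` (tibble with `recall`, `precision`),
#'   `auprc`, and the underlying `scores` tibble.
#' @export
evaluate_model <- function(model) {
  sc <- predict(model)
  y <- as.integer(sc$label == "nuclear")
  roc <- roc_curve(sc$score, y)
  pr <- pr_curve(sc$score, y)
  structure(
    list(accuracy = mean((sc$score > 0.5) == (y == 1L)),
         roc = roc, auroc = attr(roc, "auc"),
         pr = pr, auprc = attr(pr, "auc"),
         scores = sc),
    class = "loc_eval"
  )
}

#' @export
print.loc_eval <- function(x, ...) {
  cat(sprintf("<loc_eval> accuracy %.3f | AUROC %.3f | AUPRC %.3f\n",
              x$accuracy, x$auroc, x$auprc))
  invisible(x)
}

#' ROC and precision-recall curves by threshold sweep
#'
#' Thresholds sweep the distinct scores from high to low; tied scores move
#' together. Areas are trapezoidal, so the AUROC equals the
#' pairwise-concordance probability (ties counted 1/2).
#'
#' @param scores Numeric classifier scores (higher = more nuclear).
#' @param labels Binary labels (1 = nuclear).
#' @return `roc_curve`: tibble with `threshold`, `fpr`, `tpr` and
#'   attribute `auc`. `pr_curve`: tibble with `threshold`, `recall`,
#'   `precision` and attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1L)
  N <- sum(labels == 0L)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  fp <- vapply(thr, function(t) sum(scores >= t & labels == 0L), numeric(1))
  out <- tibble(threshold = c(Inf, thr),
                fpr = c(0, fp / N), tpr = c(0, tp / P))
  attr(out, "auc") <- sum(diff(out$fpr) * (head(out$tpr, -1) + tail(out$tpr, -1)) / 2)
  out
}

#' @rdname roc_curve
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  thr <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1L)
  tp <- vapply(thr, function(t) sum(scores >= t & labels == 1L), numeric(1))
  pred <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  out <- tibble(threshold = thr, recall = tp / P, precision = tp / pred)
  attr(out, "auc") <- {
    r <- c(0, out$recall)
    p <- c(out$precision[1L], out$precision)
    sum(diff(r) * (head(p, -1) + tail(p, -1)) / 2)
  }
  out
}

#' Save / load a localization model checkpoint
#'
#' Self-describing versioned JSON checkpoint (text, no serialization
#' format dependency).
#'
#' @param model A `loc_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns a
#'   `loc_model` without the cached training data.
#' @export
save_model <- function(model, path) {
  payload <- list(
    format = "nrscreen_loc_model", version = 1L,
    encoder = unclass(model$encoder), config = unclass(model$config),
    curves = model$curves, params = model$params
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(payload$format, "nrscreen_loc_model")) {
    abort("not an nrscreen model checkpoint")
  }
  as_leaf <- function(x) {
    # JSON arrays of arrays are matrices (row-major); plain arrays, vectors
    if (is.list(x) && length(x) > 0L && is.list(x[[1L]])) {
      do.call(rbind, lapply(x, function(r) unlist(r, use.names = FALSE)))
    } else {
      unlist(x, use.names = FALSE)
    }
  }
  params <- payload$params
  for (nm in setdiff(names(params), "layers")) {
    params[[nm]] <- as_leaf(params[[nm]])
  }
  params$layers <- lapply(params$layers, function(ly) lapply(ly, as_leaf))
  curves <- bind_rows(lapply(payload$curves, tibble::as_tibble))
  structure(
    list(params = params,
         curves = curves,
         encoder = structure(payload$encoder, class = "encoder_config"),
         config = structure(payload$config, class = "train_config"),
         data = NULL),
    class = "loc_model"
  )
}
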