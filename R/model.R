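#' Model configuration for the BLSTM classifier
#'
#' Defaults follow the study configuration this package implements: a single
#' bidirectional LSTM layer with tanh activation and input dropout 0.25 over
#' a frozen 100-dimensional embedding layer, trained with Adam (learning
#' rate 0.001, per-step decay 1e-6) on sparse categorical cross-entropy for
#' 20 epochs at batch size 32.  `blstm_units` (unspecified in the original
#' configuration) defaults to 100 to match the embedding dimension;
#' `max_seq_len` defaults to 300.
#'
#' @param n_classes number of output classes (required).
#' @param dim embedding dimension.
#' @param max_seq_len pad/truncate length for token sequences.
#' @param blstm_units hidden units per LSTM direction.
#' @param dropout input dropout rate in \[0, 1).
#' @param activation only `"tanh"` is supported.
#' @param optimizer only `"adam"` is supported.
#' @param learning_rate Adam learning rate.
#' @param decay per-iteration learning-rate decay.
#' @param loss only `"sparse_categorical_crossentropy"` is supported.
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param trainable_embeddings if `FALSE` (default) the embedding matrix is
#'   frozen during training.
#' @param clipnorm global gradient-norm clip applied per batch (standard
#'   protection against exploding gradients through long BPTT); 0 disables.
#' @param seed integer seed for initialization, shuffling and dropout.
#' @return an object of class `"model_config"`.
#' @export
model_config <- function(n_classes, dim = 100L, max_seq_len = 300L,
                         blstm_units = 100L, dropout = 0.25,
                         activation = "tanh", optimizer = "adam",
                         learning_rate = 0.001, decay = 1e-6,
                         loss = "sparse_categorical_crossentropy",
                         epochs = 20L, batch_size = 32L,
                         trainable_embeddings = FALSE, clipnorm = 1.0,
                         seed = 1L) {
  stopifnot(n_classes >= 1L, dim >= 1L, max_seq_len >= 1L, blstm_units >= 1L,
            dropout >= 0, dropout < 1, epochs >= 0L, batch_size >= 1L)
  if (!identical(activation, "tanh")) stop("only tanh activation is implemented")
  if (!identical(optimizer, "adam")) stop("only the adam optimizer is implemented")
  if (!identical(loss, "sparse_categorical_crossentropy")) {
    stop("only sparse categorical cross-entropy is implemented")
  }
  structure(list(n_classes = as.integer(n_classes), dim = as.integer(dim),
                 max_seq_len = as.integer(max_seq_len),
                 blstm_units = as.integer(blstm_units), dropout = dropout,
                 activation = activation, optimizer = optimizer,
                 learning_rate = learning_rate, decay = decay, loss = loss,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 trainable_embeddings = isTRUE(trainable_embeddings),
                 clipnorm = clipnorm,
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Encode a corpus into padded index sequences plus an embedding matrix
#'
#' Tokens map to 1-based vocabulary indices; sequences are right-padded with
#' 0 (or truncated) to `max_seq_len`.  Row 1 of the embedding matrix is the
#' all-zero padding row; row `i + 1` is the (weighted) vector of
#' `index_to_term[i]`, resolved through the table's OOV policy.  Tokens
#' absent from `index_to_term` (e.g. test-only terms when encoding against
#' the training vocabulary) are dropped from the sequence.
#'
#' @param corpus a corpus object.
#' @param table an embedding_table (typically a weighted one).
#' @param max_seq_len sequence length after padding/truncation.
#' @param index_to_term vocabulary defining the index space; defaults to the
#'   corpus vocabulary.  Pass the training vocabulary when encoding a test
#'   split.
#' @param classes class inventory defining label indices; defaults to the
#'   corpus classes.
#' @return an object of class `"encoded_dataset"`.
#' @export
encode <- function(corpus, table, max_seq_len, index_to_term = NULL,
                   classes = NULL) {
  if (!corpus$m) stop("cannot encode an empty corpus")
  if (is.null(index_to_term)) index_to_term <- corpus$vocabulary
  if (is.null(classes)) classes <- corpus$classes
  lab <- match(corpus$documents$label, classes)
  if (anyNA(lab)) stop("document label(s) outside the class inventory")
  seqs <- matrix(0L, nrow = corpus$m, ncol = max_seq_len)
  toks <- corpus$documents$tokens
  for (i in seq_len(corpus$m)) {
    idx <- match(toks[[i]], index_to_term)
    idx <- idx[!is.na(idx)]
    if (length(idx) > max_seq_len) idx <- idx[seq_len(max_seq_len)]
    if (length(idx)) seqs[i, seq_along(idx)] <- as.integer(idx)
  }
  emb <- rbind(numeric(table$dim), lookup(table, index_to_term))
  dimnames(emb) <- NULL
  structure(list(sequences = seqs, labels = as.integer(lab - 1L),
                 index_to_term = index_to_term, classes = classes,
                 embedding_matrix = emb, dim = table$dim,
                 max_seq_len = as.integer(max_seq_len)),
            class = "encoded_dataset")
}

#' Build an untrained BLSTM classifier
#'
#' Architecture: integer input -> embedding layer initialized from
#' `embedding_matrix` (frozen unless `trainable_embeddings`) -> one
#' bidirectional LSTM layer (tanh, input dropout, forward/backward final
#' states concatenated) -> dense softmax over `n_classes`.
#'
#' @param config a model_config.
#' @param embedding_matrix (vocab + 1) x dim matrix, row 1 all zeros.
#' @return an object of class `"blstm_model"`.
#' @export
build_blstm <- function(config, embedding_matrix) {
  if (ncol(embedding_matrix) != config$dim) {
    stop(sprintf("embedding matrix has dim %d but config says %d",
                 ncol(embedding_matrix), config$dim))
  }
  weights <- cpp_blstm_init(config$dim, config$blstm_units, config$n_classes,
                            config$seed)
  structure(list(weights = weights, config = config,
                 embedding_matrix = embedding_matrix,
                 history = NULL, classes = NULL, trained = FALSE),
            class = "blstm_model")
}

#' Train a BLSTM classifier
#'
#' Runs `config$epochs` epochs of minibatch Adam; the per-epoch history
#' records training loss/accuracy (running means over batches) and, when
#' `val_data` is given, validation loss/accuracy computed after each epoch.
#' With `epochs = 0` the model is returned untrained with an empty history.
#'
#' @param model a blstm_model from [build_blstm()].
#' @param data training encoded_dataset.
#' @param val_data optional validation encoded_dataset (must share the
#'   training vocabulary and class inventory).
#' @return the trained model, with `$history` as a tibble.
#' @export
train_blstm <- function(model, data, val_data = NULL) {
  cfg <- model$config
  if (max(data$labels) >= cfg$n_classes) {
    stop("training labels exceed n_classes")
  }
  if (!is.null(val_data)) {
    if (!identical(val_data$index_to_term, data$index_to_term)) {
      stop("val_data must be encoded with the training vocabulary")
    }
    unseen <- setdiff(unique(val_data$labels), unique(data$labels))
    if (length(unseen)) {
      warning("class(es) present in validation but absent from training: ",
              paste(data$classes[unseen + 1L], collapse = ", "))
    }
  }
  res <- cpp_blstm_fit(model$weights, model$embedding_matrix,
                       data$sequences, data$labels,
                       if (is.null(val_data)) NULL else val_data$sequences,
                       if (is.null(val_data)) NULL else val_data$labels,
                       cfg$epochs, cfg$batch_size, cfg$learning_rate,
                       cfg$decay, cfg$dropout, cfg$trainable_embeddings,
                       cfg$seed, if (is.null(cfg$clipnorm)) 1.0 else cfg$clipnorm)
  h <- res$history
  model$weights <- res$weights
  model$embedding_matrix <- res$embedding
  model$history <- tibble::tibble(
    epoch = seq_len(nrow(h)),
    train_loss = h[, 1], train_accuracy = h[, 2],
    val_loss = h[, 3], val_accuracy = h[, 4])
  model$classes <- data$classes
  model$trained <- TRUE
  model
}

#' Predict classes or probabilities with a trained BLSTM
#'
#' @param object a trained blstm_model.
#' @param data an encoded_dataset (must share the training vocabulary).
#' @param type `"class"` (default) for predicted labels as a factor, or
#'   `"prob"` for the documents-by-classes softmax matrix.
#' @param ... unused.
#' @return factor of predicted classes, or a probability matrix whose rows
#'   sum to 1.
#' @export
predict.blstm_model <- function(object, data, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$trained) && is.null(object$history)) {
    # an untrained model still produces valid softmax outputs
    object$classes <- data$classes
  }
  if (ncol(data$embedding_matrix) != object$config$dim) {
    stop("encoded data dimension does not match the model")
  }
  P <- cpp_blstm_probs(object$weights, object$embedding_matrix, data$sequences)
  classes <- if (!is.null(object$classes)) object$classes else data$classes
  colnames(P) <- classes
  if (type == "prob") return(P)
  factor(classes[max.col(P, ties.method = "first")], levels = classes)
}

#' Mean-pooled document vector
#'
#' Element-wise mean of the (weighted) vectors of a document's tokens — the
#' flat representation fed to the classical baselines.  OOV tokens follow
#' the table's policy; a document whose every token resolves to a zero
#' vector yields a zero vector with a warning.
#'
#' @param tokens character vector, the document's tokens (nonempty).
#' @param table an embedding_table.
#' @return numeric vector of length `table$dim`.
#' @export
pool_document_vector <- function(tokens, table) {
  if (!length(tokens)) stop("cannot pool an empty document")
  V <- lookup(table, tokens)
  if (is.null(dim(V))) V <- matrix(V, nrow = 1L)
  v <- colMeans(V)
  if (all(v == 0)) warning("document pooled to the zero vector")
  v
}

#' Mean-pooled vectors for every document in a corpus
#'
#' @param corpus a corpus object.
#' @param table an embedding_table.
#' @return documents-by-dim numeric matrix (empty documents become zero
#'   rows).
#' @export
pool_corpus_matrix <- function(corpus, table) {
  out <- matrix(0, nrow = corpus$m, ncol = table$dim)
  toks <- corpus$documents$tokens
  nonempty <- lengths(toks) > 0L
  rows <- suppressWarnings(
    lapply(toks[nonempty], pool_document_vector, table = table))
  if (any(nonempty)) out[nonempty, ] <- do.call(rbind, rows)
  if (!all(nonempty)) warning(sum(!nonempty), " empty documents pooled to zero")
  out
}

#' Classical machine-learning baselines over pooled vectors
#'
#' Fits each requested algorithm with its backend's default hyperparameters
#' (except k = 5 for kNN) and reports test accuracy.  Algorithms: `LR`
#' (multinomial logistic regression, `nnet::multinom`), `kNN5`
#' (`class::knn`), `RF` (`randomForest`), `SVM` (RBF `e1071::svm`),
#' `LinearSVM` (linear-kernel `e1071::svm`), `DT` (`rpart`), `MLP`
#' (`nnet`, 100 hidden units), `GNB` (Gaussian `e1071::naiveBayes`).
#'
#' @param train_x,test_x documents-by-dim feature matrices.
#' @param train_y,test_y class labels (coerced to factor over the training
#'   levels).
#' @param suite subset of the eight algorithm names.
#' @param seed seed for the stochastic learners.
#' @return named numeric vector of test accuracies.
#' @export
run_baselines <- function(train_x, train_y, test_x, test_y,
                          suite = c("LR", "kNN5", "RF", "SVM", "LinearSVM",
                                    "DT", "MLP", "GNB"),
                          seed = 1L) {
  known <- c("LR", "kNN5", "RF", "SVM", "LinearSVM", "DT", "MLP", "GNB")
  bad <- setdiff(suite, known)
  if (length(bad)) stop("unknown algorithm(s): ", paste(bad, collapse = ", "))
  train_y <- factor(train_y)
  test_y <- factor(test_y, levels = levels(train_y))
  acc <- function(pred) mean(as.character(pred) == as.character(test_y))
  if (nlevels(train_y) == 1L) {
    # degenerate single-class task: every learner predicts the sole class
    a <- acc(rep(levels(train_y), length.out = nrow(test_x)))
    return(stats::setNames(rep(a, length(suite)), suite))
  }
  train_df <- data.frame(.y = train_y, train_x)
  test_df <- data.frame(test_x)
  colnames(test_df) <- colnames(train_df)[-1L]
  out <- vapply(suite, function(alg) {
    withr::with_seed(seed, switch(alg,
      LR = {
        fit <- nnet::multinom(.y ~ ., data = train_df, trace = FALSE,
                              MaxNWts = 100000)
        acc(predict(fit, newdata = test_df))
      },
      kNN5 = acc(class::knn(train_x, test_x, train_y, k = 5)),
      RF = {
        fit <- randomForest::randomForest(x = train_x, y = train_y)
        acc(predict(fit, test_x))
      },
      SVM = {
        fit <- e1071::svm(x = train_x, y = train_y)
        acc(predict(fit, test_x))
      },
      LinearSVM = {
        fit <- e1071::svm(x = train_x, y = train_y, kernel = "linear")
        acc(predict(fit, test_x))
      },
      DT = {
        fit <- rpart::rpart(.y ~ ., data = train_df, method = "class")
        acc(predict(fit, test_df, type = "class"))
      },
      MLP = {
        fit <- nnet::nnet(x = train_x, y = stats::model.matrix(~ train_y - 1),
                          size = 100, softmax = TRUE, MaxNWts = 100000,
                          maxit = 200, trace = FALSE)
        acc(levels(train_y)[max.col(predict(fit, test_x))])
      },
      GNB = {
        fit <- e1071::naiveBayes(x = as.data.frame(train_x), y = train_y)
        acc(predict(fit, as.data.frame(test_x)))
      }))
  }, numeric(1))
  stats::setNames(out, suite)
}
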