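# Training: full analytic backprop through head, fusion and the three
# encoders, Adam updates, and evaluation over record sets. Graphs are
# built once per unique drug / protein and reused; within a batch each
# entity is encoded once and the embedding gradients of all records
# sharing it are accumulated before a single encoder backward pass.

# ---- parameter-tree utilities -------------------------------------------

.tree_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    keys <- if (!is.null(names(a))) union(names(a), names(b))
            else seq_along(a)
    for (k in keys) a[k] <- list(.tree_add(a[[k]], b[[k]]))
    a
  } else a + b
}

.adam_step <- function(p, g, s, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.null(p) || is.null(g)) return(list(p = p, s = s))
  if (is.list(p)) {
    if (is.null(s)) s <- stats::setNames(vector("list", length(p)), names(p))
    keys <- if (!is.null(names(p))) names(p) else seq_along(p)
    for (k in keys) {
      gk <- if (is.character(k) && !k %in% names(g)) NULL else g[[k]]
      r <- .adam_step(p[[k]], gk, s[[k]], lr, t, b1, b2, eps)
      p[k] <- list(r$p)
      s[k] <- list(r$s)
    }
    list(p = p, s = s)
  } else {
    if (is.null(s)) s <- list(m = p * 0, v = p * 0)
    s$m <- b1 * s$m + (1 - b1) * g
    s$v <- b2 * s$v + (1 - b2) * g^2
    mh <- s$m / (1 - b1^t)
    vh <- s$v / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
  }
}

# ---- graph preparation ---------------------------------------------------

#' Build and cache graphs for every unique drug and protein
#'
#' @param records data.frame of records (`drug_id`, `smiles`,
#'   `protein_id`, `sequence`, ...).
#' @param vocab a [feature_vocabulary()].
#' @param predictor contact predictor.
#' @param windowsize,max_direct,threshold protein graph controls.
#' @return object of class `graph_store`: `drugs` (per drug id:
#'   `list(drug = atom_graph, motif = motif_graph)`), `proteins` (per
#'   protein id: `protein_graph`), `vocab_hash`.
#' @export
prepare_graphs <- function(records, vocab = feature_vocabulary(),
                           predictor = stub_contact_predictor("banded"),
                           windowsize = 500, max_direct = 1000,
                           threshold = 0.5) {
  ud <- !duplicated(records$drug_id)
  drugs <- stats::setNames(lapply(which(ud), function(i) {
    mol <- parse_smiles(records$smiles[i])
    list(drug = build_atom_graph(mol, vocab),
         motif = build_motif_graph(mol, vocab))
  }), records$drug_id[ud])
  up <- !duplicated(records$protein_id)
  proteins <- stats::setNames(lapply(which(up), function(i) {
    cm <- splice_contact_map(records$sequence[i], predictor, windowsize,
                             max_direct)
    threshold_graph(cm, threshold)
  }), records$protein_id[up])
  structure(list(drugs = drugs, proteins = proteins,
                 vocab_hash = vocab_hash(vocab)),
            class = "graph_store")
}

.record_graphs <- function(store, drug_id, protein_id) {
  dg <- store$drugs[[drug_id]]
  if (is.null(dg)) stop_mgdta("no cached graphs for drug id '", drug_id, "'")
  pg <- store$proteins[[protein_id]]
  if (is.null(pg)) {
    stop_mgdta("no cached graph for protein id '", protein_id, "'")
  }
  list(drug = dg$drug, motif = dg$motif, protein = pg)
}

# Branch graph for one entity key "branch:id".
.branch_graph <- function(store, branch, id) {
  if (branch == "protein") store$proteins[[id]]
  else store$drugs[[id]][[branch]]
}

# ---- training ------------------------------------------------------------

#' Train a drug-target affinity model
#'
#' Minimises the mean squared error with Adam. Defaults follow the
#' published settings (2000 epochs, batch 512, learning rate 5e-4, dropout
#' already fixed in the model); pass smaller `epochs` / larger `lr` for
#' desk-scale smoke runs. All randomness (shuffling, dropout) is fixed by
#' `seed`.
#'
#' @param model a [dta_model()].
#' @param records training records.
#' @param store a [prepare_graphs()] cache for (at least) these records;
#'   built on the fly when `NULL`.
#' @param epochs,batch_size,lr optimisation settings.
#' @param seed RNG seed for shuffling and dropout.
#' @param val_records optional validation records (graphs must be in
#'   `store`); validated every `eval_every` epochs, and the best
#'   validation-MSE weights are returned as `best_model`.
#' @param eval_every validation cadence in epochs.
#' @param center_output initialise the head's output bias at the mean
#'   training label (speeds up short runs; the bias stays trainable).
#' @param verbose print a line every `eval_every` epochs.
#' @param ... passed to [prepare_graphs()] when `store` is `NULL`.
#' @return `list(model, best_model, history)`; `history` is a data.frame
#'   with per-epoch training loss (and validation MSE where computed).
#' @export
fit_dta <- function(model, records, store = NULL, epochs = 2000,
                    batch_size = 512, lr = 5e-4, seed = 1,
                    val_records = NULL, eval_every = 25,
                    center_output = TRUE, verbose = FALSE, ...) {
  if (is.null(store)) store <- prepare_graphs(records, model$vocab, ...)
  set.seed(seed)
  n <- nrow(records)
  y <- records$affinity
  if (center_output) model$fusion$bh3 <- mean(y)

  branches <- names(model$branches)
  rec_keys <- lapply(branches, function(b)
    if (b == "protein") records$protein_id else records$drug_id)
  names(rec_keys) <- branches

  opt <- list(branches = stats::setNames(vector("list", length(branches)),
                                         branches),
              fusion = NULL)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_mse = numeric(0))
  best <- list(mse = Inf, model = model)
  t_step <- 0

  for (epoch in seq_len(epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / min(batch_size, n)))
    epoch_loss <- 0
    for (batch in batches) {
      nb <- length(batch)
      fus <- model$fusion
      K <- length(branches)
      d <- fus$embed_dim
      keep <- 1 - fus$dropout
      # encode all entities a branch needs in one block-diagonal batch
      # (one forward/backward per branch), and batch records as rows of
      # matrices so the fusion/head pass is pure matrix algebra
      enc <- list()
      idx <- list()
      E <- list()
      for (b in branches) {
        ids <- unique(rec_keys[[b]][batch])
        idx[[b]] <- match(rec_keys[[b]][batch], ids)
        bg <- .batch_graphs(lapply(ids, function(id)
          .branch_graph(store, b, id)))
        enc[[b]] <- .encoder_forward(bg$X, bg$edges, bg$weights,
                                     model$branches[[b]],
                                     training = TRUE, gid = bg$gid)
        E[[b]] <- enc[[b]]$out
        if (!is.matrix(E[[b]])) E[[b]] <- matrix(E[[b]], nrow = 1)
      }

      if (fus$use_attention) {
        Q <- lapply(E, function(e) tanh(e %*% t(fus$W1)))
        ws <- lapply(Q, function(q) as.vector(q %*% fus$W2))
        Wmat <- vapply(seq_len(K), function(bi)
          ws[[bi]][idx[[branches[bi]]]], numeric(nb))
        if (nb == 1) Wmat <- matrix(Wmat, 1)
        ex <- exp(Wmat - apply(Wmat, 1, max))
        alpha <- ex / rowSums(ex)
      } else {
        alpha <- matrix(1, nb, K)
      }
      Zc <- matrix(0, nb, K * d)
      for (bi in seq_len(K)) {
        Zc[, ((bi - 1) * d + 1):(bi * d)] <-
          alpha[, bi] * E[[bi]][idx[[branches[bi]]], , drop = FALSE]
      }

      H1pre <- sweep(Zc %*% fus$Wh1, 2, fus$bh1, `+`)
      M1 <- matrix((stats::runif(length(H1pre)) < keep) / keep, nb)
      H1 <- relu(H1pre) * M1
      H2pre <- sweep(H1 %*% fus$Wh2, 2, fus$bh2, `+`)
      M2 <- matrix((stats::runif(length(H2pre)) < keep) / keep, nb)
      H2 <- relu(H2pre) * M2
      yhat <- as.vector(H2 %*% fus$Wh3) + fus$bh3

      err <- yhat - y[batch]
      epoch_loss <- epoch_loss + sum(err^2)
      if (!is.finite(epoch_loss)) {
        stop_mgdta("training diverged (non-finite loss) at epoch ", epoch)
      }
      dy <- 2 * err / nb

      g_fusion <- list(Wh3 = crossprod(H2, dy), bh3 = sum(dy))
      dH2pre <- (dy %o% as.vector(fus$Wh3)) * M2 * (H2pre > 0)
      g_fusion$Wh2 <- crossprod(H1, dH2pre)
      g_fusion$bh2 <- colSums(dH2pre)
      dH1pre <- (dH2pre %*% t(fus$Wh2)) * M1 * (H1pre > 0)
      g_fusion$Wh1 <- crossprod(Zc, dH1pre)
      g_fusion$bh1 <- colSums(dH1pre)
      dZc <- dH1pre %*% t(fus$Wh1)

      dalpha <- matrix(0, nb, K)
      dz_rec <- vector("list", K)
      for (bi in seq_len(K)) {
        sl <- ((bi - 1) * d + 1):(bi * d)
        Eb <- E[[bi]][idx[[branches[bi]]], , drop = FALSE]
        dalpha[, bi] <- rowSums(dZc[, sl, drop = FALSE] * Eb)
        dz_rec[[bi]] <- alpha[, bi] * dZc[, sl, drop = FALSE]
      }
      if (fus$use_attention) {
        dW <- alpha * (dalpha - rowSums(alpha * dalpha))
        gW1 <- matrix(0, nrow(fus$W1), ncol(fus$W1))
        gW2 <- numeric(length(fus$W2))
        for (bi in seq_len(K)) {
          dws <- rowsum(dW[, bi], idx[[branches[bi]]])[, 1]
          # rowsum orders by sorted group; ids are 1..n_entities
          Qb <- Q[[bi]]
          gW2 <- gW2 + as.vector(crossprod(Qb, dws))
          dQpre <- (dws %o% fus$W2) * (1 - Qb^2)
          gW1 <- gW1 + crossprod(dQpre, E[[bi]])
          dz_rec[[bi]] <- list(rec = dz_rec[[bi]], ent = dQpre %*% fus$W1)
        }
        g_fusion$W1 <- gW1
        g_fusion$W2 <- gW2
      }

      t_step <- t_step + 1
      for (bi in seq_len(K)) {
        b <- branches[bi]
        dz_part <- dz_rec[[bi]]
        dz_ent <- if (is.list(dz_part) && !is.null(dz_part$ent)) {
          rowsum(dz_part$rec, idx[[b]]) + dz_part$ent
        } else {
          rowsum(dz_part, idx[[b]])
        }
        g_branch <- .encoder_backward(dz_ent, enc[[b]]$cache,
                                      model$branches[[b]])
        upd <- .adam_step(.learnable(model$branches[[b]]), g_branch,
                          opt$branches[[b]], lr, t_step)
        for (f in names(upd$p)) model$branches[[b]][[f]] <- upd$p[[f]]
        opt$branches[[b]] <- upd$s
      }
      upd <- .adam_step(.learnable(model$fusion), g_fusion, opt$fusion,
                        lr, t_step)
      for (f in names(upd$p)) model$fusion[[f]] <- upd$p[[f]]
      opt$fusion <- upd$s
    }
    loss <- epoch_loss / n
    val_mse <- NA_real_
    if (epoch %% eval_every == 0 || epoch == epochs) {
      if (!is.null(val_records)) {
        val_mse <- mse(val_records$affinity,
                       predict_records(model, val_records, store))
        if (val_mse < best$mse) best <- list(mse = val_mse, model = model)
      }
      if (verbose) {
        message(sprintf("epoch %d: train loss %.4f%s", epoch, loss,
                        if (is.na(val_mse)) ""
                        else sprintf(", val MSE %.4f", val_mse)))
      }
    }
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = loss,
                                val_mse = val_mse))
  }
  if (is.null(val_records)) best$model <- model
  list(model = model, best_model = best$model, history = history)
}

#' Predict affinities for a record set
#'
#' @param model a `dta_model`.
#' @param records data.frame of records.
#' @param store graph cache from [prepare_graphs()]; built when `NULL`.
#' @param ... passed to [prepare_graphs()] when `store` is `NULL`.
#' @return numeric vector of predictions (evaluation mode).
#' @export
predict_records <- function(model, records, store = NULL, ...) {
  if (is.null(store)) store <- prepare_graphs(records, model$vocab, ...)
  if (!identical(store$vocab_hash, model$config$vocab_hash)) {
    stop_mgdta("graph store was built with a different feature ",
               "vocabulary than the model (hash mismatch)")
  }
  branches <- names(model$branches)
  fus <- model$fusion
  K <- length(branches)
  d <- fus$embed_dim
  nr <- nrow(records)
  E <- list()
  idx <- list()
  for (b in branches) {
    keys <- if (b == "protein") records$protein_id else records$drug_id
    ids <- unique(keys)
    idx[[b]] <- match(keys, ids)
    bg <- .batch_graphs(lapply(ids, function(id)
      .branch_graph(store, b, id)))
    out <- .encoder_forward(bg$X, bg$edges, bg$weights,
                            model$branches[[b]], training = FALSE,
                            gid = bg$gid)$out
    E[[b]] <- if (is.matrix(out)) out else matrix(out, nrow = 1)
  }
  if (fus$use_attention) {
    ws <- lapply(E, function(e)
      as.vector(tanh(e %*% t(fus$W1)) %*% fus$W2))
    Wmat <- vapply(seq_len(K), function(bi)
      ws[[bi]][idx[[branches[bi]]]], numeric(nr))
    if (nr == 1) Wmat <- matrix(Wmat, 1)
    ex <- exp(Wmat - apply(Wmat, 1, max))
    alpha <- ex / rowSums(ex)
  } else {
    alpha <- matrix(1, nr, K)
  }
  Zc <- matrix(0, nr, K * d)
  for (bi in seq_len(K)) {
    Zc[, ((bi - 1) * d + 1):(bi * d)] <-
      alpha[, bi] * E[[bi]][idx[[branches[bi]]], , drop = FALSE]
  }
  H1 <- relu(sweep(Zc %*% fus$Wh1, 2, fus$bh1, `+`))
  H2 <- relu(sweep(H1 %*% fus$Wh2, 2, fus$bh2, `+`))
  as.vector(H2 %*% fus$Wh3) + fus$bh3
}

#' Evaluate a model on a record set
#'
#' @inheritParams predict_records
#' @return `list(metrics = <mse/ci/rm2/pearson>, predictions)`.
#' @export
evaluate_dta <- function(model, records, store = NULL, ...) {
  p <- predict_records(model, records, store, ...)
  list(metrics = evaluate_predictions(records$affinity, p),
       predictions = p)
}
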