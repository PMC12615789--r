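# Multi-modal Temporal-Spatial Vision Transformer (MTSViT): seasonal
# reflectance and topography streams are patch-embedded, passed through
# shared spatial and temporal encoders, time-pooled, fused with a location
# token in a self-attention decoder, and mapped by an MLP head to per-pixel
# class logits.

#' MTSViT hyperparameter configuration
#'
#' Defaults are the full-scale architecture (embedding 192, 6 heads, spatial
#' and temporal encoder depth 2, decoder depth 4, MLP dimension 768, 8x8
#' spatial patches, temporal patch 1, 8 target classes on 128x128 scenes).
#' Desk-scale experiments shrink \code{embed_dim}, depths and
#' \code{image_size}.
#'
#' @param embed_dim token embedding size; divisible by \code{heads}.
#' @param heads number of attention heads.
#' @param spatial_depth,temporal_depth,decoder_depth transformer depths.
#' @param mlp_dim hidden width of the block MLPs and of the segmentation
#'   head.
#' @param spatial_patch square patch side in pixels; must divide
#'   \code{image_size}.
#' @param temporal_patch temporal patch length (1 = one token per season).
#' @param n_classes number of target classes (unknown is never predicted).
#' @param image_size scene side in pixels.
#' @param s2_bands,topo_bands,n_times input tensor shapes.
#' @return Object of class \code{mtsvit_config}.
#' @export
mtsvit_config <- function(embed_dim = 192, heads = 6, spatial_depth = 2,
                          temporal_depth = 2, decoder_depth = 4,
                          mlp_dim = 768, spatial_patch = 8,
                          temporal_patch = 1, n_classes = 8,
                          image_size = 128, s2_bands = 10, topo_bands = 3,
                          n_times = 4) {
  if (image_size %% spatial_patch != 0)
    stop_invalid("image_size must be divisible by spatial_patch")
  if (embed_dim %% heads != 0)
    stop_invalid("embed_dim must be divisible by heads")
  if (temporal_patch != 1)
    stop_invalid("only temporal_patch = 1 is supported")
  structure(list(embed_dim = embed_dim, heads = heads,
                 spatial_depth = spatial_depth,
                 temporal_depth = temporal_depth,
                 decoder_depth = decoder_depth, mlp_dim = mlp_dim,
                 spatial_patch = spatial_patch,
                 temporal_patch = temporal_patch, n_classes = n_classes,
                 image_size = image_size, s2_bands = s2_bands,
                 topo_bands = topo_bands, n_times = n_times),
            class = "mtsvit_config")
}

n_tokens <- function(config) (config$image_size %/% config$spatial_patch)^2

#' Split an image into flattened square patches
#'
#' Tokens are ordered row-major over the patch grid; each token is the
#' column-major flattening of its \code{patch x patch x bands} block.
#' \code{unpatchify} is the exact inverse.
#'
#' @param image numeric array \code{(rows, cols, bands)} (a matrix is
#'   treated as a single band).
#' @param patch square patch side; must divide both image dimensions.
#' @return Matrix \code{(n_tokens, patch * patch * bands)}.
#' @export
patchify <- function(image, patch) {
  if (is.matrix(image)) dim(image) <- c(dim(image), 1)
  d <- dim(image)
  if (d[1] %% patch != 0 || d[2] %% patch != 0)
    stop_invalid("image dimensions (%d x %d) not divisible by patch %d",
                 d[1], d[2], patch)
  gr <- d[1] %/% patch; gc <- d[2] %/% patch
  out <- matrix(0, gr * gc, patch * patch * d[3])
  t <- 0
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    t <- t + 1
    out[t, ] <- as.vector(image[(patch * i - patch + 1):(patch * i),
                                (patch * j - patch + 1):(patch * j), ,
                                drop = FALSE])
  }
  out
}

#' @rdname patchify
#' @param tokens matrix produced by \code{patchify} (or head outputs of the
#'   same layout).
#' @param rows,cols,bands target image shape.
#' @export
unpatchify <- function(tokens, rows, cols, bands, patch) {
  gr <- rows %/% patch; gc <- cols %/% patch
  stopifnot(nrow(tokens) == gr * gc,
            ncol(tokens) == patch * patch * bands)
  out <- array(0, c(rows, cols, bands))
  t <- 0
  for (i in seq_len(gr)) for (j in seq_len(gc)) {
    t <- t + 1
    out[(patch * i - patch + 1):(patch * i),
        (patch * j - patch + 1):(patch * j), ] <-
      array(tokens[t, ], c(patch, patch, bands))
  }
  out
}

init_block <- function(D, mlp, sd = 0.02) {
  list(ln1g = rep(1, D), ln1b = rep(0, D),
       Wqkv = matrix(stats::rnorm(D * 3 * D, sd = sd), D),
       bqkv = rep(0, 3 * D),
       Wo = matrix(stats::rnorm(D * D, sd = sd), D), bo = rep(0, D),
       ln2g = rep(1, D), ln2b = rep(0, D),
       W1 = matrix(stats::rnorm(D * mlp, sd = sd), D), b1 = rep(0, mlp),
       W2 = matrix(stats::rnorm(mlp * D, sd = sd), mlp), b2 = rep(0, D))
}

#' Initialize MTSViT weights
#'
#' Gaussian init (sd 0.02) for projections and embeddings, identity
#' layer norms, zero biases. Deterministic given the seed.
#'
#' @param config a \code{\link{mtsvit_config}}.
#' @param seed RNG seed.
#' @param norm optional normalization statistics (list with \code{s2_mean},
#'   \code{s2_sd}, \code{topo_mean}, \code{topo_sd}) stored with the
#'   weights; identity statistics when omitted.
#' @return Object of class \code{mtsvit_weights}: \code{params} (nested
#'   list), \code{config}, \code{norm}.
#' @export
mtsvit_init <- function(config, seed = 1, norm = NULL) {
  D <- config$embed_dim; mlp <- config$mlp_dim; N <- n_tokens(config)
  ps2 <- config$spatial_patch^2 * config$s2_bands
  ptp <- config$spatial_patch^2 * config$topo_bands
  phead <- config$spatial_patch^2 * config$n_classes
  with_seed(seed, {
    params <- list(
      s2_embed = list(W = matrix(stats::rnorm(ps2 * D, sd = 0.02), ps2),
                      b = rep(0, D)),
      topo_embed = list(W = matrix(stats::rnorm(ptp * D, sd = 0.02), ptp),
                        b = rep(0, D)),
      pos = matrix(stats::rnorm(N * D, sd = 0.02), N),
      temb = matrix(stats::rnorm(config$n_times * D, sd = 0.02),
                    config$n_times),
      loc_proj = list(W = matrix(stats::rnorm(3 * D, sd = 0.02), 3),
                      b = rep(0, D)),
      spatial = lapply(seq_len(config$spatial_depth),
                       function(i) init_block(D, mlp)),
      temporal = lapply(seq_len(config$temporal_depth),
                        function(i) init_block(D, mlp)),
      decoder = lapply(seq_len(config$decoder_depth),
                       function(i) init_block(D, mlp)),
      final_ln = list(g = rep(1, D), b = rep(0, D)),
      head = list(W1 = matrix(stats::rnorm(D * mlp, sd = 0.02), D),
                  b1 = rep(0, mlp),
                  W2 = matrix(stats::rnorm(mlp * phead, sd = 0.02), mlp),
                  b2 = rep(0, phead)))
    if (is.null(norm))
      norm <- list(s2_mean = rep(0, config$s2_bands),
                   s2_sd = rep(1, config$s2_bands),
                   topo_mean = rep(0, config$topo_bands),
                   topo_sd = rep(1, config$topo_bands))
    structure(list(params = params, config = config, norm = norm),
              class = "mtsvit_weights")
  })
}

#' Number of learned parameters
#' @param weights a \code{mtsvit_weights} object.
#' @return Integer parameter count.
#' @export
mtsvit_n_params <- function(weights) length(tree_unlist(weights$params))

# standardize inputs with the stored per-band statistics
normalize_inputs <- function(sample, norm) {
  s2 <- sample$s2; topo <- sample$topo
  for (b in seq_len(dim(s2)[4]))
    s2[, , , b] <- (s2[, , , b] - norm$s2_mean[b]) / norm$s2_sd[b]
  for (b in seq_len(dim(topo)[4]))
    topo[, , , b] <- (topo[, , , b] - norm$topo_mean[b]) / norm$topo_sd[b]
  list(s2 = s2, topo = topo)
}

check_sample_shapes <- function(sample, config) {
  d <- dim(sample$s2)
  if (!all(d == c(config$n_times, config$image_size, config$image_size,
                  config$s2_bands)))
    stop_invalid("s2 tensor is (%s); config expects (%d, %d, %d, %d)",
                 paste(d, collapse = ", "), config$n_times,
                 config$image_size, config$image_size, config$s2_bands)
  dt <- dim(sample$topo)
  if (!all(dt == c(1, config$image_size, config$image_size,
                   config$topo_bands)))
    stop_invalid("topo tensor is (%s); config expects (1, %d, %d, %d)",
                 paste(dt, collapse = ", "), config$image_size,
                 config$image_size, config$topo_bands)
  if (length(sample$loc) != 3) stop_invalid("loc must be a 3-vector")
  if (!all(is.finite(sample$s2)) || !all(is.finite(sample$topo)) ||
      !all(is.finite(sample$loc)))
    stop_invalid("non-finite values in model inputs")
  invisible(TRUE)
}

#' MTSViT forward pass
#'
#' Embeds each seasonal composite and the topography stack into patch
#' tokens (shared learned positional embeddings, learned temporal
#' embeddings; topography uses temporal index 1), runs the shared spatial
#' encoder per (modality, time), the shared temporal encoder per (modality,
#' spatial token), mean-pools the spectral stream over time, decodes the
#' fused token set (spectral tokens, topography tokens, one projected
#' location token) with self-attention, and maps each decoded spectral
#' token to \code{patch^2 * n_classes} logits.
#'
#' @param sample a \code{scene_sample} (labels are never read).
#' @param weights a \code{mtsvit_weights} object.
#' @param keep_cache keep all intermediate activations for
#'   backpropagation (internal use).
#' @return Numeric array \code{(image_size, image_size, n_classes)} of
#'   logits; with \code{keep_cache = TRUE}, a list \code{(logits, cache)}.
#' @export
mtsvit_forward <- function(sample, weights, keep_cache = FALSE) {
  config <- weights$config
  check_sample_shapes(sample, config)
  p <- weights$params
  D <- config$embed_dim; N <- n_tokens(config)
  P <- config$spatial_patch; Ti <- config$n_times
  nin <- normalize_inputs(sample, weights$norm)

  # patch embedding per modality and time step
  seqs <- vector("list", Ti + 1)
  xtok <- vector("list", Ti + 1)
  for (t in seq_len(Ti)) {
    xtok[[t]] <- patchify(nin$s2[t, , , ], P)
    seqs[[t]] <- linear_f(xtok[[t]], p$s2_embed$W, p$s2_embed$b) + p$pos +
      matrix(p$temb[t, ], N, D, byrow = TRUE)
  }
  xtok[[Ti + 1]] <- patchify(nin$topo[1, , , ], P)
  seqs[[Ti + 1]] <- linear_f(xtok[[Ti + 1]], p$topo_embed$W,
                             p$topo_embed$b) + p$pos +
    matrix(p$temb[1, ], N, D, byrow = TRUE)

  # shared spatial encoder, applied independently per sequence
  sp_cache <- vector("list", Ti + 1)
  for (s in seq_along(seqs)) {
    cc <- vector("list", config$spatial_depth)
    for (l in seq_along(p$spatial)) {
      r <- block_f(seqs[[s]], p$spatial[[l]], config$heads)
      seqs[[s]] <- r$y; cc[[l]] <- r$cache
    }
    sp_cache[[s]] <- cc
  }

  # shared temporal encoder: spectral stream (N, Ti, D), topo stream (N, 1, D)
  s2t <- array(0, c(N, Ti, D))
  for (t in seq_len(Ti)) s2t[, t, ] <- seqs[[t]]
  tpt <- array(seqs[[Ti + 1]], c(N, 1, D))
  tc_s2 <- vector("list", config$temporal_depth)
  tc_tp <- vector("list", config$temporal_depth)
  for (l in seq_along(p$temporal)) {
    r <- block_time_f(s2t, p$temporal[[l]], config$heads)
    s2t <- r$y; tc_s2[[l]] <- r$cache
    r <- block_time_f(tpt, p$temporal[[l]], config$heads)
    tpt <- r$y; tc_tp[[l]] <- r$cache
  }
  s2_tok <- apply(s2t, c(1, 3), mean)      # time pooling
  topo_tok <- matrix(tpt, N, D)

  # multi-modal decoder over spectral + topo + location tokens
  loc_tok <- linear_f(matrix(sample$loc, 1), p$loc_proj$W, p$loc_proj$b)
  dec <- rbind(s2_tok, topo_tok, loc_tok)
  dc <- vector("list", config$decoder_depth)
  for (l in seq_along(p$decoder)) {
    r <- block_f(dec, p$decoder[[l]], config$heads)
    dec <- r$y; dc[[l]] <- r$cache
  }

  # segmentation head on the decoded spectral tokens
  fin <- layernorm_f(dec[seq_len(N), , drop = FALSE], p$final_ln$g,
                     p$final_ln$b)
  h1 <- linear_f(fin$y, p$head$W1, p$head$b1)
  a1 <- gelu_f(h1)
  out_tok <- linear_f(a1, p$head$W2, p$head$b2)
  logits <- unpatchify(out_tok, config$image_size, config$image_size,
                       config$n_classes, P)
  if (!keep_cache) return(logits)
  list(logits = logits,
       cache = list(xtok = xtok, sp = sp_cache, tc_s2 = tc_s2,
                    tc_tp = tc_tp, s2t_dims = c(N, Ti, D), dec = dc,
                    fin = fin, h1 = h1, a1 = a1, loc = sample$loc, N = N))
}

# backward pass: dlogits (H, W, C) -> gradient tree matching weights$params
mtsvit_backward <- function(dlogits, weights, cache) {
  config <- weights$config; p <- weights$params
  D <- config$embed_dim; N <- cache$N; P <- config$spatial_patch
  Ti <- config$n_times
  dtok <- patchify(dlogits, P)              # inverse of unpatchify layout

  g <- list()
  l2b <- linear_b(dtok, cache$a1, p$head$W2)
  dh1 <- gelu_b(l2b$dx, cache$h1)
  l1b <- linear_b(dh1, cache$fin$y, p$head$W1)
  g$head <- list(W1 = l1b$dW, b1 = l1b$db, W2 = l2b$dW, b2 = l2b$db)
  lnf <- layernorm_b(l1b$dx, cache$fin, p$final_ln$g)
  g$final_ln <- list(g = lnf$dg, b = lnf$db)

  ddec <- matrix(0, 2 * N + 1, D)
  ddec[seq_len(N), ] <- lnf$dx
  g$decoder <- vector("list", config$decoder_depth)
  for (l in rev(seq_along(p$decoder))) {
    r <- block_b(ddec, p$decoder[[l]], cache$dec[[l]], config$heads)
    ddec <- r$dx; g$decoder[[l]] <- r$g
  }
  dloc_tok <- ddec[2 * N + 1, , drop = FALSE]
  lb <- linear_b(dloc_tok, matrix(cache$loc, 1), p$loc_proj$W)
  g$loc_proj <- list(W = lb$dW, b = lb$db)

  ds2_tok <- ddec[seq_len(N), , drop = FALSE]
  dtopo_tok <- ddec[N + seq_len(N), , drop = FALSE]
  ds2t <- array(0, c(N, Ti, D))
  for (t in seq_len(Ti)) ds2t[, t, ] <- ds2_tok / Ti   # time-pool backward
  dtpt <- array(dtopo_tok, c(N, 1, D))

  g$temporal <- vector("list", config$temporal_depth)
  for (l in rev(seq_along(p$temporal))) {
    r1 <- block_time_b(ds2t, p$temporal[[l]], cache$tc_s2[[l]], config$heads)
    r2 <- block_time_b(dtpt, p$temporal[[l]], cache$tc_tp[[l]], config$heads)
    ds2t <- r1$dx; dtpt <- r2$dx
    g$temporal[[l]] <- tree_map2(`+`, r1$g, r2$g)
  }

  dseqs <- vector("list", Ti + 1)
  for (t in seq_len(Ti)) dseqs[[t]] <- matrix(ds2t[, t, ], N, D)
  dseqs[[Ti + 1]] <- matrix(dtpt, N, D)

  g$spatial <- vector("list", config$spatial_depth)
  for (s in seq_len(Ti + 1)) {
    dx <- dseqs[[s]]
    for (l in rev(seq_along(p$spatial))) {
      r <- block_b(dx, p$spatial[[l]], cache$sp[[s]][[l]], config$heads)
      dx <- r$dx
      g$spatial[[l]] <- if (is.null(g$spatial[[l]])) r$g
        else tree_map2(`+`, g$spatial[[l]], r$g)
    }
    dseqs[[s]] <- dx
  }

  g$pos <- Reduce(`+`, dseqs)
  g$temb <- matrix(0, Ti, D)
  for (t in seq_len(Ti)) g$temb[t, ] <- colSums(dseqs[[t]])
  g$temb[1, ] <- g$temb[1, ] + colSums(dseqs[[Ti + 1]])
  se <- list(dW = 0, db = 0)
  for (t in seq_len(Ti)) {
    se$dW <- se$dW + crossprod(cache$xtok[[t]], dseqs[[t]])
    se$db <- se$db + colSums(dseqs[[t]])
  }
  g$s2_embed <- list(W = se$dW, b = se$db)
  g$topo_embed <- list(W = crossprod(cache$xtok[[Ti + 1]], dseqs[[Ti + 1]]),
                       b = colSums(dseqs[[Ti + 1]]))
  g[names(p)]   # order like params
}

#' Softmax class probabilities from logits
#' @param logits array \code{(H, W, C)}.
#' @return Array of the same shape; each pixel sums to 1.
#' @export
softmax_probs <- function(logits) {
  d <- dim(logits)
  m <- array(apply(logits, c(1, 2), max), d[1:2])
  e <- exp(logits - as.vector(m))
  s <- apply(e, c(1, 2), sum)
  e / as.vector(s)
}

#' Ensemble prediction by softmax averaging
#'
#' Runs every ensemble member on the sample and returns the arithmetic mean
#' of their per-pixel softmax probabilities (not the softmax of mean
#' logits).
#'
#' @param models list of \code{mtsvit_weights} with identical
#'   configurations.
#' @param sample a \code{scene_sample}.
#' @return Array \code{(H, W, n_classes)} of class probabilities.
#' @export
ensemble_predict <- function(models, sample) {
  if (length(models) < 1) stop_invalid("need at least one model")
  cfg <- models[[1]]$config
  for (m in models)
    if (!identical(unclass(m$config), unclass(cfg)))
      stop_invalid("ensemble members have heterogeneous configurations")
  probs <- 0
  for (m in models) probs <- probs + softmax_probs(mtsvit_forward(sample, m))
  probs / length(models)
}

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized archive embedding the weights, the
#' configuration and the normalization statistics; the round trip is
#' bit-identical.
#'
#' @param weights a \code{mtsvit_weights} object.
#' @param path file path.
#' @return \code{load_checkpoint} returns the \code{mtsvit_weights}.
#' @export
save_checkpoint <- function(weights, path) {
  saveRDS(weights, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  w <- readRDS(path)
  if (!inherits(w, "mtsvit_weights")) stop_invalid("not an MTSViT checkpoint")
  w
}
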