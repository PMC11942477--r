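#' Model configuration
#'
#' Shape-and-size contract for the dual-modality model.  The published-scale
#' defaults are a 768-dimensional, 12-layer sequence encoder and a 4-stage
#' vision encoder with 2, 2, 6, 2 shifted-window blocks; [toy_model_config()]
#' gives a CPU-trainable reduction.  The vision encoder downsamples the
#' L x L feature image by `patch_size` at the embedding step and by 2 at
#' each of the `length(depths) - 1` patch-merging steps; with the default
#' patch size 2 and 4 stages the final grid is (L/16) x (L/16), which is
#' mean-pooled along one axis into `Lv = L/16` fusion tokens.  Stage widths
#' double at each merge and end at `d_model`.
#'
#' @param L Sequence length (must be divisible by the total downsampling
#'   factor and by 16).
#' @param k k-mer size for the sequence branch.
#' @param d_model Embedding dimension D shared by both branches.
#' @param heads Attention head count (divides every stage width).
#' @param n_seq_layers Transformer encoder layers in the sequence branch.
#' @param depths Blocks per vision stage.
#' @param patch_size Patch-embedding downsampling factor.
#' @param window Target attention window; each stage uses the largest
#'   divisor of its grid not exceeding this.
#' @param fusion_layers Number of self-/cross-attention fusion blocks.
#' @param dropout Dropout probability used during training.
#' @return List of class `"model_config"` with derived fields `Lt` (token
#'   count), `G` (per-stage grids), `C` (per-stage widths), `win`, `shift`,
#'   and `Lv`.
#' @export
model_config <- function(L = 112L, k = 3L, d_model = 768L, heads = 12L,
                         n_seq_layers = 12L, depths = c(2L, 2L, 6L, 2L),
                         patch_size = 2L, window = 7L, fusion_layers = 2L,
                         dropout = 0.1) {
  L <- as.integer(L); k <- as.integer(k)
  S <- length(depths)
  down <- patch_size * 2^(S - 1L)
  if (L %% 16L != 0L) stop("L must be divisible by 16")
  if (L %% down != 0L) stop("L must be divisible by the total downsampling ",
                            "factor ", down)
  if (d_model %% heads != 0L) stop("d_model must be divisible by heads")
  C <- d_model / 2^((S - 1L):0L)
  if (any(C %% heads != 0L))
    stop("every stage width must be divisible by heads; got widths ",
         paste(C, collapse = ","))
  if (k < 1L || k > L) stop("k must satisfy 1 <= k <= L")
  G <- (L / patch_size) / 2^(0:(S - 1L))
  if (any(G < 1L)) stop("too many stages for this L")
  win <- vapply(G, function(g) {
    divs <- which(g %% seq_len(g) == 0)
    max(divs[divs <= window])
  }, numeric(1))
  shift <- ifelse(win < G, win %/% 2, 0)
  structure(list(L = L, k = k, d_model = as.integer(d_model),
                 heads = as.integer(heads),
                 n_seq_layers = as.integer(n_seq_layers),
                 depths = as.integer(depths), patch_size = as.integer(patch_size),
                 window = as.integer(window),
                 fusion_layers = as.integer(fusion_layers), dropout = dropout,
                 Lt = L - k + 3L, S = S, G = as.integer(G), C = as.integer(C),
                 win = as.integer(win), shift = as.integer(shift),
                 down = as.integer(down), Lv = as.integer(G[S])),
            class = "model_config")
}

#' @param ... Overrides passed to [model_config()].
#' @rdname model_config
#' @export
toy_model_config <- function(...) {
  args <- list(...)
  defaults <- list(L = 112L, k = 3L, d_model = 64L, heads = 8L,
                   n_seq_layers = 2L, depths = c(2L, 2L), patch_size = 4L,
                   window = 7L, fusion_layers = 2L, dropout = 0.1)
  do.call(model_config, utils::modifyList(defaults, args))
}

#' @export
print.model_config <- function(x, ...) {
  cat("<model_config> L =", x$L, " k =", x$k, " D =", x$d_model,
      " heads =", x$heads, "\n")
  cat("  sequence: ", x$n_seq_layers, "layers,", x$Lt, "tokens\n")
  cat("  vision:   depths", paste(x$depths, collapse = ","),
      " grids", paste(x$G, collapse = ","),
      " widths", paste(x$C, collapse = ","), " Lv =", x$Lv, "\n")
  invisible(x)
}

# ---- parameter initialization --------------------------------------------

tn <- function(nr, nc, sd = 0.02) matrix(stats::rnorm(nr * nc, 0, sd), nr, nc)

init_mha <- function(p, prefix, d_in, d) {
  p[[paste0(prefix, ".Wq")]] <- tn(d_in, d); p[[paste0(prefix, ".bq")]] <- numeric(d)
  p[[paste0(prefix, ".Wk")]] <- tn(d_in, d); p[[paste0(prefix, ".bk")]] <- numeric(d)
  p[[paste0(prefix, ".Wv")]] <- tn(d_in, d); p[[paste0(prefix, ".bv")]] <- numeric(d)
  p[[paste0(prefix, ".Wo")]] <- tn(d, d); p[[paste0(prefix, ".bo")]] <- numeric(d)
  p
}

init_ln <- function(p, prefix, d) {
  p[[paste0(prefix, ".g")]] <- rep(1, d)
  p[[paste0(prefix, ".b")]] <- numeric(d)
  p
}

init_ffn <- function(p, prefix, d, hidden = 4L * d) {
  p[[paste0(prefix, ".W1")]] <- tn(d, hidden); p[[paste0(prefix, ".b1")]] <- numeric(hidden)
  p[[paste0(prefix, ".W2")]] <- tn(hidden, d); p[[paste0(prefix, ".b2")]] <- numeric(d)
  p
}

init_params <- function(cfg, task, n_classes, seed) {
  with_seed(seed, {
    p <- list()
    D <- cfg$d_model
    vocab <- build_vocab(cfg$k)
    # sequence branch
    p$seq.emb <- tn(length(vocab), D)
    p$seq.pos <- tn(cfg$Lt, D)
    p <- init_ln(p, "seq.eln", D)
    for (i in seq_len(cfg$n_seq_layers)) {
      pre <- paste0("seq.l", i)
      p <- init_mha(p, pre, D, D)
      p <- init_ln(p, paste0(pre, ".ln1"), D)
      p <- init_ffn(p, paste0(pre, ".f"), D)
      p <- init_ln(p, paste0(pre, ".ln2"), D)
    }
    # vision branch
    C1 <- cfg$C[1]
    p$vis.embed.W <- tn(24L * cfg$patch_size^2, C1)
    p$vis.embed.b <- numeric(C1)
    p <- init_ln(p, "vis.eln", C1)
    for (s in seq_len(cfg$S)) {
      Cs <- cfg$C[s]
      for (i in seq_len(cfg$depths[s])) {
        pre <- paste0("vis.s", s, ".b", i)
        p <- init_ln(p, paste0(pre, ".ln1"), Cs)
        p <- init_mha(p, pre, Cs, Cs)
        p <- init_ln(p, paste0(pre, ".ln2"), Cs)
        p <- init_ffn(p, paste0(pre, ".f"), Cs)
      }
      if (s < cfg$S) {
        p <- init_ln(p, paste0("vis.m", s, ".ln"), 4L * Cs)
        p[[paste0("vis.m", s, ".W")]] <- tn(4L * Cs, 2L * Cs)
      }
    }
    if (task == "classify") {
      for (f in seq_len(cfg$fusion_layers)) {
        for (m in c("t", "v")) {
          pre <- paste0("fus.f", f, ".", m)
          p <- init_mha(p, paste0(pre, ".sa"), D, D)
          p <- init_mha(p, paste0(pre, ".ca"), D, D)
          p[[paste0(pre, ".lin.W")]] <- tn(2L * D, D)
          p[[paste0(pre, ".lin.b")]] <- numeric(D)
          p <- init_ln(p, paste0(pre, ".ln"), D)
        }
      }
      p$cls.W <- tn(D, n_classes)
      p$cls.b <- numeric(n_classes)
    } else {
      p <- init_mha(p, "rss.ca", D, D)
      for (s in seq_len(cfg$S - 1L)) {
        Cs <- cfg$C[s]
        p[[paste0("rss.up", s, ".W")]] <- tn(cfg$C[s + 1L], 4L * Cs)
        p[[paste0("rss.up", s, ".b")]] <- numeric(4L * Cs)
      }
      cf <- 8L
      p$rss.up0.W <- tn(cfg$C[1], cfg$patch_size^2 * cf)
      p$rss.up0.b <- numeric(cfg$patch_size^2 * cf)
      p$rss.out.W <- tn(cf, 1L)
      p$rss.out.b <- numeric(1L)
    }
    p
  })
}

#' Construct a dual-modality model
#'
#' Initializes all parameters of the sequence encoder, the shifted-window
#' vision encoder and the requested downstream head with a fixed seed
#' (truncated-normal-style 0.02-sd weights, unit layer-norm gains).
#'
#' @param cfg A [model_config()].
#' @param task `"classify"` (sequence classification / interaction) or
#'   `"rss"` (secondary-structure head).
#' @param n_classes Number of classes for the classification head.
#' @param seed Integer seed for the parameter draw.
#' @return List of class `"duet_model"` with fields `cfg`, `task`,
#'   `n_classes`, `params`, `vocab` and an index cache.
#' @export
duet_model <- function(cfg = toy_model_config(), task = c("classify", "rss"),
                       n_classes = 2L, seed = 1L) {
  task <- match.arg(task)
  if (task == "classify" && n_classes < 2L) stop("n_classes must be >= 2")
  m <- list(cfg = cfg, task = task, n_classes = as.integer(n_classes),
            params = init_params(cfg, task, n_classes, seed),
            vocab = build_vocab(cfg$k),
            cache = new.env(parent = emptyenv()))
  class(m) <- "duet_model"
  m
}

#' @export
print.duet_model <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat("<duet_model> task =", x$task, " parameters =", format(np, big.mark = ","), "\n")
  print(x$cfg)
  invisible(x)
}

# ---- index helpers (cached per model) ------------------------------------

model_cache <- function(model, key, builder) {
  v <- model$cache[[key]]
  if (is.null(v)) {
    v <- builder()
    assign(key, v, envir = model$cache)
  }
  v
}

# Window partition for a G x G grid, window w, cyclic shift s, batch B.
# Token (b, r, c) lives at row (b-1)G^2 + (r-1)G + c.  Returns the gather
# order into window-major layout, its inverse, block sizes, and the
# additive cross-boundary masks for shifted windows.
window_index <- function(G, w, s, B) {
  nwin <- (G / w)^2
  r <- rep(rep(seq_len(G), each = G), B)       # row-major within sample
  c <- rep(rep(seq_len(G), times = G), B)
  b <- rep(seq_len(B), each = G * G)
  sr <- (r - 1L - s) %% G
  sc <- (c - 1L - s) %% G
  win <- (sr %/% w) * (G / w) + (sc %/% w)     # 0-based window within sample
  pos <- (sr %% w) * w + (sc %% w)             # 0-based position in window
  target <- (b - 1L) * G * G + win * w * w + pos + 1L
  ord <- integer(B * G * G)
  ord[target] <- seq_len(B * G * G)
  inv <- integer(B * G * G)
  inv[ord] <- seq_len(B * G * G)
  out <- list(order = ord, inv = inv, nq = w * w,
              nblocks = as.integer(B * nwin), mask = NULL, mask_idx = NULL)
  if (s > 0) {
    # group per axis: tokens wrapped by the cyclic shift vs not
    grp <- function(shifted) as.integer(shifted >= G - s)
    mask <- array(0, c(w * w, w * w, nwin))
    for (wr in 0:(G / w - 1L)) for (wc in 0:(G / w - 1L)) {
      srow <- wr * w + 0:(w - 1L)
      scol <- wc * w + 0:(w - 1L)
      gid <- outer(grp(srow) * 2L, rep(1L, w)) + outer(rep(1L, w), grp(scol))
      gid <- as.vector(t(gid))                 # window-internal row-major
      mask[, , wr * (G / w) + wc + 1L] <- ifelse(outer(gid, gid, "!="), -1e9, 0)
    }
    out$mask <- mask
    out$mask_idx <- rep(seq_len(nwin), times = B)
  }
  out
}

# 2x2 patch-merging gather indices: 4 vectors, one per quadrant.
merge_index <- function(G, B) {
  H <- G / 2L
  r2 <- rep(rep(seq_len(H), each = H), B)
  c2 <- rep(rep(seq_len(H), times = H), B)
  b <- rep(seq_len(B), each = H * H)
  idx <- function(dr, dc) (b - 1L) * G * G + (2L * r2 - 2L + dr) * G +
    (2L * c2 - 1L + dc)
  list(idx(0L, 0L), idx(0L, 1L), idx(1L, 0L), idx(1L, 1L))
}

# Inverse of merging: map rows of f^2 stacked quadrant slices (each at grid
# G) onto the (B*(fG)^2)-row layout of grid f*G.
unmerge_perm <- function(G, f, B) {
  n <- B * G * G
  FG <- f * G
  r <- rep(rep(seq_len(FG), each = FG), B)
  c <- rep(rep(seq_len(FG), times = FG), B)
  b <- rep(seq_len(B), each = FG * FG)
  r1 <- (r - 1L) %/% f + 1L; dr <- (r - 1L) %% f
  c1 <- (c - 1L) %/% f + 1L; dc <- (c - 1L) %% f
  q <- dr * f + dc                              # 0-based quadrant
  q * n + (b - 1L) * G * G + (r1 - 1L) * G + c1
}

# ---- shared forward building blocks --------------------------------------

new_tape <- function(model) {
  e <- new.env(parent = emptyenv())
  e$nodes <- new.env(parent = emptyenv())
  e$model <- model
  e$attn <- list()
  e
}

P <- function(tape, name) {
  n <- tape$nodes[[name]]
  if (is.null(n)) {
    v <- tape$model$params[[name]]
    if (is.null(v)) stop("unknown parameter: ", name)
    n <- ad_node(v, param_name = name)
    tape$nodes[[name]] <- n
  }
  n
}

collect_grads <- function(tape) {
  out <- list()
  for (nm in ls(tape$nodes)) {
    g <- tape$nodes[[nm]]$grad
    if (!is.null(g)) out[[nm]] <- g
  }
  out
}

mha_block <- function(tape, prefix, q_in, kv_in, nq, nk, heads,
                      mask = NULL, mask_idx = NULL, record = NULL,
                      name = NULL) {
  q <- ad_linear(q_in, P(tape, paste0(prefix, ".Wq")), P(tape, paste0(prefix, ".bq")))
  k <- ad_linear(kv_in, P(tape, paste0(prefix, ".Wk")), P(tape, paste0(prefix, ".bk")))
  v <- ad_linear(kv_in, P(tape, paste0(prefix, ".Wv")), P(tape, paste0(prefix, ".bv")))
  o <- ad_attention(q, k, v, nq, nk, heads, mask, mask_idx, record, name)
  ad_linear(o, P(tape, paste0(prefix, ".Wo")), P(tape, paste0(prefix, ".bo")))
}

ffn_block <- function(tape, prefix, x) {
  h <- ad_gelu(ad_linear(x, P(tape, paste0(prefix, ".W1")),
                         P(tape, paste0(prefix, ".b1"))))
  ad_linear(h, P(tape, paste0(prefix, ".W2")), P(tape, paste0(prefix, ".b2")))
}

ln_block <- function(tape, prefix, x) {
  ad_layernorm(x, P(tape, paste0(prefix, ".g")), P(tape, paste0(prefix, ".b")))
}

# Patch-embedding input: stacks (list of L x L x 24 arrays) -> constant
# matrix (B * (L/p)^2) x (24 p^2), rows in (b, r, c) order.
patch_input <- function(stacks, p) {
  do.call(rbind, lapply(stacks, function(st) {
    L <- dim(st)[1]
    G <- L / p
    a <- array(unclass(st), c(p, G, p, G, 24L))   # (pr, r, pc, c, ch)
    b <- aperm(a, c(4L, 2L, 1L, 3L, 5L))          # (c, r, pr, pc, ch)
    dim(b) <- c(G * G, p * p * 24L)
    b
  }))
}

# Vision encoder forward.  Returns the final-stage token node plus (when
# wanted) the per-stage outputs for the U-Net decoder.
fwd_vision <- function(model, tape, X0, B, training = FALSE,
                       want_stages = FALSE, record = NULL) {
  cfg <- model$cfg
  x <- ad_linear(nd(X0), P(tape, "vis.embed.W"), P(tape, "vis.embed.b"))
  x <- ln_block(tape, "vis.eln", x)
  stages <- vector("list", cfg$S)
  for (s in seq_len(cfg$S)) {
    G <- cfg$G[s]; w <- cfg$win[s]
    for (i in seq_len(cfg$depths[s])) {
      sh <- if (i %% 2L == 0L) cfg$shift[s] else 0L
      wi <- model_cache(model, sprintf("win.%d.%d.%d", G, sh, B),
                        function() window_index(G, w, sh, B))
      pre <- sprintf("vis.s%d.b%d", s, i)
      y <- ln_block(tape, paste0(pre, ".ln1"), x)
      y <- ad_gather_rows(y, wi$order)
      y <- mha_block(tape, pre, y, y, wi$nq, wi$nq, cfg$heads,
                     mask = wi$mask, mask_idx = wi$mask_idx,
                     record = record, name = pre)
      y <- ad_gather_rows(y, wi$inv)
      x <- ad_add(x, ad_dropout(y, cfg$dropout, training))
      z <- ffn_block(tape, paste0(pre, ".f"),
                     ln_block(tape, paste0(pre, ".ln2"), x))
      x <- ad_add(x, ad_dropout(z, cfg$dropout, training))
    }
    stages[[s]] <- x
    if (s < cfg$S) {
      mi <- model_cache(model, sprintf("merge.%d.%d", G, B),
                        function() merge_index(G, B))
      x <- ad_concat_cols(
        ad_concat_cols(ad_gather_rows(x, mi[[1]]), ad_gather_rows(x, mi[[2]])),
        ad_concat_cols(ad_gather_rows(x, mi[[3]]), ad_gather_rows(x, mi[[4]])))
      x <- ln_block(tape, sprintf("vis.m%d.ln", s), x)
      x <- ad_matmul(x, P(tape, sprintf("vis.m%d.W", s)))
    }
  }
  # pool the (G x G) grid along the column axis: Lv = G tokens per sample
  G <- cfg$G[cfg$S]
  groups <- rep(seq_len(B * G), each = G)
  vl <- ad_group_mean(x, groups, B * G)
  list(vl = vl, stages = if (want_stages) stages else NULL)
}

# Sequence encoder forward over an id matrix (B x Lt).
fwd_sequence <- function(model, tape, ids, training = FALSE, pad = NULL,
                         record = NULL) {
  cfg <- model$cfg
  B <- nrow(ids)
  Lt <- ncol(ids)
  if (Lt != cfg$Lt) stop("token count ", Lt, " does not match config Lt = ", cfg$Lt)
  if (any(ids < 1L | ids > nrow(model$params$seq.emb)))
    stop("token id out of vocabulary range")
  x <- ad_add(ad_gather_rows(P(tape, "seq.emb"), as.vector(t(ids))),
              ad_gather_rows(P(tape, "seq.pos"), rep(seq_len(Lt), B)))
  x <- ad_dropout(ln_block(tape, "seq.eln", x), cfg$dropout, training)
  mask <- NULL; mask_idx <- NULL
  if (!is.null(pad) && any(pad)) {
    mask <- array(0, c(Lt, Lt, B))
    for (bb in seq_len(B)) mask[, pad[bb, ], bb] <- -1e9
    mask_idx <- seq_len(B)
  }
  for (i in seq_len(cfg$n_seq_layers)) {
    pre <- paste0("seq.l", i)
    a <- mha_block(tape, pre, x, x, Lt, Lt, cfg$heads,
                   mask = mask, mask_idx = mask_idx,
                   record = record, name = pre)
    x <- ln_block(tape, paste0(pre, ".ln1"),
                  ad_add(x, ad_dropout(a, cfg$dropout, training)))
    f <- ffn_block(tape, paste0(pre, ".f"), x)
    x <- ln_block(tape, paste0(pre, ".ln2"),
                  ad_add(x, ad_dropout(f, cfg$dropout, training)))
  }
  x
}

# One self-/cross-attention fusion layer applied to both modalities.
fwd_fusion_layer <- function(model, tape, f, Tn, Vn, B, training) {
  cfg <- model$cfg
  Lt <- cfg$Lt; Lv <- cfg$Lv
  one <- function(m, x, other, nq, nk) {
    pre <- sprintf("fus.f%d.%s", f, m)
    sa <- mha_block(tape, paste0(pre, ".sa"), x, x, nq, nq, cfg$heads)
    ca <- mha_block(tape, paste0(pre, ".ca"), x, other, nq, nk, cfg$heads)
    h <- ad_linear(ad_concat_cols(sa, ca),
                   P(tape, paste0(pre, ".lin.W")), P(tape, paste0(pre, ".lin.b")))
    ad_selu(ln_block(tape, paste0(pre, ".ln"), h))
  }
  newT <- one("t", Tn, Vn, Lt, Lv)
  newV <- one("v", Vn, Tn, Lv, Lt)
  list(T = ad_dropout(newT, cfg$dropout, training),
       V = ad_dropout(newV, cfg$dropout, training))
}

fwd_fusion <- function(model, tape, Tn, Vn, B, training = FALSE) {
  for (f in seq_len(model$cfg$fusion_layers)) {
    out <- fwd_fusion_layer(model, tape, f, Tn, Vn, B, training)
    Tn <- out$T; Vn <- out$V
  }
  list(T = Tn, V = Vn)
}

# Classification head: token-axis concatenation, mean pool, linear.
fwd_classify <- function(model, tape, Tn, Vn, B) {
  cfg <- model$cfg
  allrows <- ad_rbind(list(Tn, Vn))
  groups <- c(rep(seq_len(B), each = cfg$Lt), rep(seq_len(B), each = cfg$Lv))
  pooled <- ad_group_mean(allrows, groups, B)
  ad_linear(pooled, P(tape, "cls.W"), P(tape, "cls.b"))
}

# Structure head: U-Net decoder over the vision stages with a bottleneck
# cross-attention against the sequence embedding.
fwd_rss <- function(model, tape, X0, ids, B, training = FALSE) {
  cfg <- model$cfg
  Tn <- fwd_sequence(model, tape, ids, training)
  vis <- fwd_vision(model, tape, X0, B, training, want_stages = TRUE)
  xs <- vis$stages
  GS <- cfg$G[cfg$S]
  y <- ad_add(xs[[cfg$S]],
              mha_block(tape, "rss.ca", xs[[cfg$S]], Tn,
                        GS * GS, cfg$Lt, cfg$heads))
  upsample <- function(y, W, b, G, f) {
    U <- ad_linear(y, P(tape, W), P(tape, b))
    Cout <- ncol(U$value) / f^2
    slices <- lapply(seq_len(f^2), function(q)
      ad_slice_cols(U, (q - 1L) * Cout + seq_len(Cout)))
    perm <- model_cache(model, sprintf("unmerge.%d.%d.%d", G, f, B),
                        function() unmerge_perm(G, f, B))
    ad_gather_rows(ad_rbind(slices), perm)
  }
  for (s in rev(seq_len(cfg$S - 1L))) {
    y <- upsample(y, sprintf("rss.up%d.W", s), sprintf("rss.up%d.b", s),
                  cfg$G[s + 1L], 2L)
    y <- ad_add(y, xs[[s]])
  }
  y <- upsample(y, "rss.up0.W", "rss.up0.b", cfg$G[1], cfg$patch_size)
  ad_linear(y, P(tape, "rss.out.W"), P(tape, "rss.out.b"))  # (B*L^2) x 1
}

# ---- public encoder / head wrappers --------------------------------------

prepare_ids <- function(model, seqs) {
  cfg <- model$cfg
  seqs <- if (is.character(seqs) && !is.list(seqs)) as.list(seqs) else seqs
  ids <- t(vapply(seqs, function(s) {
    s <- unclass(as_rna_sequence(s))
    n <- nchar(s)
    if (n > cfg$L) s <- substr(s, 1L, cfg$L)
    if (nchar(s) < cfg$L) s <- paste0(s, strrep("N", cfg$L - nchar(s)))
    encode_tokens(tokenize_kmers(s, cfg$k), model$vocab)
  }, integer(cfg$Lt)))
  if (length(seqs) == 1L) ids <- matrix(ids, nrow = 1L)
  ids
}

as_stack_list <- function(stacks) {
  if (inherits(stacks, "feature_stack") ||
      (is.array(stacks) && length(dim(stacks)) == 3L)) list(stacks) else stacks
}

#' Encode feature stacks with the vision branch
#'
#' Runs the hierarchical shifted-window encoder over one or more 24-channel
#' feature stacks and returns the `Lv x D` vision embedding(s): the final
#' grid mean-pooled along one spatial axis.
#'
#' @param model A [duet_model()].
#' @param stacks A `feature_stack` (L x L x 24 array) or list of them.
#' @param return_attention Also return the per-block window attention cubes.
#' @return An `Lv x D` matrix for a single stack, a list of them otherwise;
#'   with `return_attention = TRUE`, a list with `embedding` and `attention`.
#' @export
vision_encode <- function(model, stacks, return_attention = FALSE) {
  stacks <- as_stack_list(stacks)
  cfg <- model$cfg
  L <- dim(stacks[[1]])[1]
  if (L %% 16L != 0L) stop("L must be divisible by 16")
  if (L != cfg$L) stop("stack size ", L, " does not match config L = ", cfg$L)
  B <- length(stacks)
  tape <- new_tape(model)
  record <- if (return_attention) tape else NULL
  out <- fwd_vision(model, tape, patch_input(stacks, cfg$patch_size), B,
                    training = FALSE, record = record)
  emb <- split_rows(out$vl$value, B)
  if (B == 1L) emb <- emb[[1]]
  if (return_attention) list(embedding = emb, attention = tape$attn) else emb
}

#' Encode sequences with the sequence branch
#'
#' Tokenizes to overlapping k-mers (with `[CLS]`/`[SEP]`), embeds, and runs
#' the transformer encoder layers.
#'
#' @param model A [duet_model()].
#' @param seqs Character vector of sequences (truncated / N-padded to L).
#' @param return_attention Also return per-layer attention cubes.
#' @return An `Lt x D` matrix for a single sequence, a list otherwise.
#' @export
sequence_encode <- function(model, seqs, return_attention = FALSE) {
  ids <- prepare_ids(model, seqs)
  tape <- new_tape(model)
  record <- if (return_attention) tape else NULL
  x <- fwd_sequence(model, tape, ids, training = FALSE, record = record)
  emb <- split_rows(x$value, nrow(ids))
  if (nrow(ids) == 1L) emb <- emb[[1]]
  if (return_attention) list(embedding = emb, attention = tape$attn) else emb
}

split_rows <- function(m, B) {
  n <- nrow(m) / B
  lapply(seq_len(B), function(b) m[(b - 1L) * n + seq_len(n), , drop = FALSE])
}

#' Fuse sequence and vision embeddings
#'
#' Applies the configured number of fusion blocks.  Each block computes,
#' per modality, self-attention and cross-attention to the other modality,
#' concatenates the two along the feature axis, and applies a linear map
#' back to D, layer normalization and SeLU.  Shapes are preserved.
#'
#' @param model A [duet_model()] with task `"classify"`.
#' @param Tl `Lt x D` sequence embedding.
#' @param Vl `Lv x D` vision embedding.
#' @return List with fused `Tl` and `Vl`.
#' @export
fuse_embeddings <- function(model, Tl, Vl) {
  if (model$task != "classify") stop("fusion parameters exist for the classify task")
  tape <- new_tape(model)
  out <- fwd_fusion(model, tape, nd(Tl), nd(Vl), 1L, training = FALSE)
  list(Tl = out$T$value, Vl = out$V$value)
}

#' Classification head
#'
#' Concatenates the fused sequence and vision tokens along the token axis
#' (`C = Lt + Lv` pooled positions), averages them, and applies the linear
#' classifier with a softmax.
#'
#' @param model A [duet_model()] with task `"classify"`.
#' @param Tl,Vl Fused embeddings from [fuse_embeddings()].
#' @return Named numeric vector of class probabilities (sums to 1), with
#'   attribute `pooled_positions` = Lt + Lv.
#' @export
classify_head <- function(model, Tl, Vl) {
  tape <- new_tape(model)
  logits <- fwd_classify(model, tape, nd(Tl), nd(Vl), 1L)
  z <- logits$value[1, ]
  p <- exp(z - max(z)); p <- p / sum(p)
  structure(p, pooled_positions = model$cfg$Lt + model$cfg$Lv)
}

#' Secondary-structure head
#'
#' Encoder-decoder (U-Net) pass: the vision stages downsample the feature
#' image, a bottleneck cross-attention against the sequence embedding
#' transforms the coarsest features without resampling, and transposed-
#' convolution-style upsampling with skip connections restores the L x L
#' resolution.  The single-channel output goes through a sigmoid and is
#' symmetrized as (P + t(P)) / 2.
#'
#' @param model A [duet_model()] with task `"rss"`.
#' @param stack A `feature_stack` for one sequence.
#' @param seq The corresponding sequence (for the sequence branch).
#' @return Symmetric L x L matrix of pair probabilities in `[0, 1]`.
#' @export
rss_head <- function(model, stack, seq) {
  if (model$task != "rss") stop("model was not built with the rss head")
  cfg <- model$cfg
  L <- dim(stack)[1]
  if (L %% 16L != 0L) stop("L must be divisible by 16")
  tape <- new_tape(model)
  ids <- prepare_ids(model, seq)
  logits <- fwd_rss(model, tape, patch_input(as_stack_list(stack), cfg$patch_size),
                    ids, 1L, training = FALSE)
  pm <- matrix(as.vector(logits$value), cfg$L, cfg$L, byrow = TRUE)
  pm <- 1 / (1 + exp(-pm))
  (pm + t(pm)) / 2
}

#' Scaled-dot-product attention
#'
#' Multi-head attention between a query source and a key/value source:
#' per head `softmax(Q K' / sqrt(dk)) V`, heads concatenated and linearly
#' projected.  With `weights = NULL` all projections are identities, which
#' makes the operation the bare attention average of `kv_src` rows.
#' Setting `q_src = kv_src` gives self-attention; distinct sources give
#' cross-attention.
#'
#' @param q_src `Nq x D` query-source matrix.
#' @param kv_src `Nk x D` key/value-source matrix (same D).
#' @param heads Head count (divides D).
#' @param weights Optional list with `Wq, Wk, Wv, Wo` (`D x D`) and biases
#'   `bq, bk, bv, bo` (length D).
#' @param return_attention Also return the `Nq x Nk x heads` weight cube.
#' @return `Nq x D` matrix, or a list with `output` and `attention`.
#' @export
attend <- function(q_src, kv_src, heads = 1L, weights = NULL,
                   return_attention = FALSE) {
  if (ncol(q_src) != ncol(kv_src))
    stop("q_src and kv_src must share the feature dimension")
  D <- ncol(q_src)
  if (D %% heads != 0L) stop("feature dimension must be divisible by heads")
  pr <- function(x, W, b) sweep(x %*% W, 2L, b, "+")
  if (is.null(weights)) {
    q <- q_src; k <- kv_src; v <- kv_src
  } else {
    q <- pr(q_src, weights$Wq, weights$bq)
    k <- pr(kv_src, weights$Wk, weights$bk)
    v <- pr(kv_src, weights$Wv, weights$bv)
  }
  fw <- attn_fwd_cpp(q, k, v, nrow(q_src), nrow(kv_src), heads,
                     array(0, c(0, 0, 0)), integer(0), want_A = TRUE)
  out <- fw$O
  if (!is.null(weights)) out <- pr(out, weights$Wo, weights$bo)
  if (return_attention) list(output = out, attention = fw$A) else out
}

#' Random attention projection weights
#'
#' @param D Feature dimension.
#' @param seed Integer seed.
#' @return Weight list consumable by [attend()].
#' @export
attend_weights <- function(D, seed = 1L) {
  with_seed(seed, list(Wq = tn(D, D), bq = numeric(D),
                       Wk = tn(D, D), bk = numeric(D),
                       Wv = tn(D, D), bv = numeric(D),
                       Wo = tn(D, D), bo = numeric(D)))
}

#' Attention distance and entropy diagnostics
#'
#' For each head, the mean over queries of the attention-weighted distance
#' to the keys and of the row entropy `-sum(a log a)` — the standard
#' locality/focus diagnostics for attention maps.
#'
#' @param attn `Nq x Nk x H` attention cube (rows sum to 1) or a list of
#'   `Nq x Nk` matrices.
#' @param q_coords,k_coords Numeric positions of queries and keys
#'   (`k_coords` defaults to `q_coords`).
#' @return Data frame with columns `head`, `mean_distance`, `mean_entropy`.
#' @export
attention_stats <- function(attn, q_coords, k_coords = q_coords) {
  if (is.list(attn)) attn <- simplify2array(attn)
  if (length(dim(attn)) == 2L) attn <- array(attn, c(dim(attn), 1L))
  H <- dim(attn)[3]
  if (max(abs(apply(attn, 3L, rowSums) - 1)) > 1e-6)
    stop("attention rows must sum to 1")
  dmat <- abs(outer(q_coords, k_coords, "-"))
  res <- t(vapply(seq_len(H), function(h) {
    A <- attn[, , h]
    al <- ifelse(A > 0, A * log(A), 0)
    c(mean(rowSums(A * dmat)), mean(-rowSums(al)))
  }, numeric(2)))
  data.frame(head = seq_len(H), mean_distance = res[, 1],
             mean_entropy = res[, 2])
}

#' Cross-entropy losses
#'
#' `bce_loss` is the mean binary cross-entropy between predicted
#' probabilities and 0/1 targets; `multiclass_ce` is the mean negative
#' log-likelihood of the true class under a predicted probability matrix.
#' Probabilities are clipped at 1e-12.
#'
#' @param pred Probabilities (vector/matrix for `bce_loss`; `n x K` matrix
#'   for `multiclass_ce`).
#' @param target 0/1 values of the same shape, or integer class indices.
#' @return Nonnegative scalar loss.
#' @export
bce_loss <- function(pred, target) {
  if (length(pred) != length(target)) stop("pred and target shapes differ")
  p <- pmin(pmax(as.vector(pred), 1e-12), 1 - 1e-12)
  t <- as.vector(target)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' @rdname bce_loss
#' @export
multiclass_ce <- function(pred, target) {
  pred <- rbind(pred)
  if (nrow(pred) != length(target)) stop("pred and target shapes differ")
  p <- pmax(pred[cbind(seq_len(nrow(pred)), as.integer(target))], 1e-12)
  -mean(log(p))
}
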