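#' The 14 canonical infant body parts
#'
#' Part order is fixed and used everywhere a per-part vector or list is
#' indexed.
#' @return Character vector of part names.
#' @export
infant_parts <- function() {
  c("head", "neck",
    "l_shoulder", "r_shoulder", "l_elbow", "r_elbow", "l_hand", "r_hand",
    "l_hip", "r_hip", "l_knee", "r_knee", "l_foot", "r_foot")
}

#' Construct a kinematic tree over body parts
#'
#' @param parts Character vector of part names.
#' @param parent Named character vector mapping each non-root part to its
#'   parent; the root maps to `NA`.
#' @return An object of class `kinematic_tree` with `parts`, `parent`,
#'   `root`, `children` and a topological part order (`order`, parents
#'   before children).
#' @export
kinematic_tree <- function(parts, parent) {
  parent <- parent[parts]
  names(parent) <- parts
  root <- parts[is.na(parent)]
  if (length(root) != 1L) stop("tree must have exactly one root")
  if (!all(parent[!is.na(parent)] %in% parts)) stop("unknown parent part")
  # topological order by repeated sweeps; also detects cycles/disconnection
  ord <- root
  repeat {
    nxt <- parts[!(parts %in% ord) & parent[parts] %in% ord]
    if (!length(nxt)) break
    ord <- c(ord, nxt)
  }
  if (length(ord) != length(parts)) stop("tree must be connected and acyclic")
  children <- lapply(parts, function(p) parts[!is.na(parent) & parent == p])
  names(children) <- parts
  structure(list(parts = parts, parent = parent, root = root,
                 children = children, order = ord),
            class = "kinematic_tree")
}

#' The default infant kinematic tree
#'
#' Head is the root; the neck hangs off the head and carries both shoulders
#' and both hips; arms chain shoulder - elbow - hand and legs chain
#' hip - knee - foot.
#' @return A [kinematic_tree()].
#' @export
infant_tree <- function() {
  p <- c(head = NA, neck = "head",
         l_shoulder = "neck", r_shoulder = "neck",
         l_elbow = "l_shoulder", r_elbow = "r_shoulder",
         l_hand = "l_elbow", r_hand = "r_elbow",
         l_hip = "neck", r_hip = "neck",
         l_knee = "l_hip", r_knee = "r_hip",
         l_foot = "l_knee", r_foot = "r_knee")
  kinematic_tree(infant_parts(), p)
}

#' Default feature settings for a body model
#'
#' @param cell_size_px HOG cell side in pixels.
#' @param bins Orientation bins per cell (the per-cell feature dimension).
#' @param normalize HOG normalization scheme.
#' @param interval Pyramid levels per octave.
#' @param min_level_px Smallest pyramid level side in pixels.
#' @param patch_cells Part template side in cells (5).
#' @param train_scale Canonical working scale: positives are warped to
#'   `train_scale` times the size given by the quantile box rule, and
#'   detection pyramids start at this scale.  Values above 1 add an
#'   upsampled bottom octave, which refines placement quantization for
#'   small subjects.
#' @return A named list.
#' @export
feature_config <- function(cell_size_px = 8L, bins = 9L, normalize = "cell",
                           interval = 2L, min_level_px = 5L * cell_size_px,
                           patch_cells = 5L, train_scale = 1) {
  list(cell_size_px = as.integer(cell_size_px), bins = as.integer(bins),
       normalize = normalize, interval = as.integer(interval),
       min_level_px = as.integer(min_level_px),
       patch_cells = as.integer(patch_cells),
       train_scale = as.numeric(train_scale))
}

MODEL_VERSION <- "babydpm-model-1"

#' Construct an (untrained) body model
#'
#' Holds one part filter per (part, state), quadratic spring deformation
#' parameters and continuous anchor offsets per edge and state pair, state
#' co-occurrence priors (unary and pairwise), and a global bias.  Filters
#' and co-occurrence tables start at zero; deformations start at the
#' conventional `[0, 0, 0.01, 0.01]` (zero linear terms, weak isotropic
#' quadratic spring).
#'
#' @param tree A [kinematic_tree()].
#' @param states Named integer vector: number of mixture states per part.
#' @param config Feature settings from [feature_config()].
#' @return An object of class `body_model`.
#' @export
body_model <- function(tree = infant_tree(),
                       states = stats::setNames(rep(1L, length(tree$parts)), tree$parts),
                       config = feature_config()) {
  states <- as.integer(states[tree$parts])
  names(states) <- tree$parts
  if (any(is.na(states) | states < 1L)) stop("states must be positive for every part")
  pc <- config$patch_cells
  d <- config$bins
  filters <- lapply(tree$parts, function(p)
    lapply(seq_len(states[[p]]), function(s) array(0, c(pc, pc, d))))
  names(filters) <- tree$parts
  nonroot <- setdiff(tree$order, tree$root)
  zeta <- lapply(nonroot, function(ch) {
    sp <- states[[tree$parent[[ch]]]]
    z <- array(0, c(states[[ch]], sp, 4L))
    z[, , 3L] <- 0.01
    z[, , 4L] <- 0.01
    z
  })
  names(zeta) <- nonroot
  anchor <- lapply(nonroot, function(ch)
    array(0, c(states[[ch]], states[[tree$parent[[ch]]]], 2L)))
  names(anchor) <- nonroot
  unary <- lapply(tree$parts, function(p) numeric(states[[p]]))
  names(unary) <- tree$parts
  pairwise <- lapply(nonroot, function(ch)
    matrix(0, states[[ch]], states[[tree$parent[[ch]]]]))
  names(pairwise) <- nonroot
  structure(list(tree = tree, states = states, filters = filters,
                 zeta = zeta, anchor = anchor, unary = unary,
                 pairwise = pairwise, bias = 0,
                 omega_score = stats::setNames(rep(-Inf, length(tree$parts)), tree$parts),
                 config = config, version = MODEL_VERSION),
            class = "body_model")
}

#' @export
print.body_model <- function(x, ...) {
  cat(sprintf("<body_model> %d parts, states %s, %d parameters, cell %d px\n",
              length(x$tree$parts),
              paste(range(x$states), collapse = "-"),
              length(model_beta(x)), x$config$cell_size_px))
  invisible(x)
}

# Parameter layout: offsets of every weight block inside the flat vector
# beta.  Order: all filters (parts in canonical order, states within part),
# then deformations per non-root part, then unary co-occurrence per part,
# then pairwise co-occurrence per non-root part, then the bias.
beta_layout <- function(model) {
  off <- 0L
  filt <- list()
  pc <- model$config$patch_cells; d <- model$config$bins
  flen <- pc * pc * d
  for (p in model$tree$parts) {
    filt[[p]] <- integer(model$states[[p]])
    for (s in seq_len(model$states[[p]])) {
      filt[[p]][s] <- off
      off <- off + flen
    }
  }
  nonroot <- setdiff(model$tree$order, model$tree$root)
  zeta <- list(); unary <- list(); pairw <- list()
  for (ch in nonroot) {
    zeta[[ch]] <- off
    off <- off + length(model$zeta[[ch]])
  }
  for (p in model$tree$parts) {
    unary[[p]] <- off
    off <- off + model$states[[p]]
  }
  for (ch in nonroot) {
    pairw[[ch]] <- off
    off <- off + length(model$pairwise[[ch]])
  }
  list(filters = filt, zeta = zeta, unary = unary, pairwise = pairw,
       bias = off, length = off + 1L, filter_len = flen)
}

#' Flatten a body model's learnable parameters to a vector
#'
#' The score of a full configuration is linear in this vector, which is what
#' the structured SVM optimizes.  [model_set_beta()] is its exact inverse.
#'
#' @param model A [body_model()].
#' @return Numeric parameter vector.
#' @export
model_beta <- function(model) {
  lay <- beta_layout(model)
  beta <- numeric(lay$length)
  for (p in model$tree$parts)
    for (s in seq_len(model$states[[p]]))
      beta[lay$filters[[p]][s] + seq_len(lay$filter_len)] <- as.vector(model$filters[[p]][[s]])
  for (ch in names(lay$zeta))
    beta[lay$zeta[[ch]] + seq_along(model$zeta[[ch]])] <- as.vector(model$zeta[[ch]])
  for (p in model$tree$parts)
    beta[lay$unary[[p]] + seq_len(model$states[[p]])] <- model$unary[[p]]
  for (ch in names(lay$pairwise))
    beta[lay$pairwise[[ch]] + seq_along(model$pairwise[[ch]])] <- as.vector(model$pairwise[[ch]])
  beta[lay$bias + 1L] <- model$bias
  beta
}

#' Write a flat parameter vector back into a body model
#'
#' @param model A [body_model()] giving the shapes.
#' @param beta Numeric vector of length `length(model_beta(model))`.
#' @return The model with updated weights.
#' @export
model_set_beta <- function(model, beta) {
  lay <- beta_layout(model)
  if (length(beta) != lay$length)
    stop(sprintf("beta has length %d, model expects %d", length(beta), lay$length))
  pc <- model$config$patch_cells; d <- model$config$bins
  for (p in model$tree$parts)
    for (s in seq_len(model$states[[p]]))
      model$filters[[p]][[s]] <- array(beta[lay$filters[[p]][s] + seq_len(lay$filter_len)],
                                       c(pc, pc, d))
  for (ch in names(lay$zeta))
    model$zeta[[ch]] <- array(beta[lay$zeta[[ch]] + seq_along(model$zeta[[ch]])],
                              dim(model$zeta[[ch]]))
  for (p in model$tree$parts)
    model$unary[[p]] <- beta[lay$unary[[p]] + seq_len(model$states[[p]])]
  for (ch in names(lay$pairwise))
    model$pairwise[[ch]] <- matrix(beta[lay$pairwise[[ch]] + seq_along(model$pairwise[[ch]])],
                                   nrow(model$pairwise[[ch]]))
  beta_bias <- beta[lay$bias + 1L]
  model$bias <- beta_bias
  model
}

#' Score one full part configuration (reference path)
#'
#' Sums, term by term, the part-filter responses, the spring deformation
#' scores along every edge, the state co-occurrence priors and the bias for
#' a complete placement of all parts.  This plain-R sum is the reference
#' total that dynamic-programming inference must reproduce.
#'
#' @param model A [body_model()].
#' @param level A [hog_level()] whose feature settings match the model.
#' @param placements Data frame with one row per part: columns `part`,
#'   `state`, `x`, `y` (0-based anchor cell coordinates at this level).
#' @return The scalar configuration score.
#' @export
score_configuration <- function(model, level, placements) {
  parts <- model$tree$parts
  if (!all(parts %in% placements$part))
    stop("placements must cover every part of the model")
  pl <- placements[match(parts, placements$part), , drop = FALSE]
  pc <- model$config$patch_cells
  dlev <- dim(level$cells)
  if (any(pl$x < 0 | pl$y < 0 | pl$x + pc > dlev[2L] | pl$y + pc > dlev[1L]))
    stop("placement footprint out of bounds")
  total <- model$bias
  for (i in seq_along(parts)) {
    p <- parts[i]; s <- pl$state[i]
    patch <- level$cells[pl$y[i] + seq_len(pc), pl$x[i] + seq_len(pc), , drop = FALSE]
    total <- total + sum(model$filters[[p]][[s]] * patch) + model$unary[[p]][s]
  }
  for (ch in setdiff(model$tree$order, model$tree$root)) {
    pa <- model$tree$parent[[ch]]
    ic <- match(ch, parts); ip <- match(pa, parts)
    sc <- pl$state[ic]; sp <- pl$state[ip]
    dxy <- c(pl$x[ic] - pl$x[ip], pl$y[ic] - pl$y[ip]) - model$anchor[[ch]][sc, sp, ]
    total <- total - sum(model$zeta[[ch]][sc, sp, ] * c(dxy, dxy^2)) +
      model$pairwise[[ch]][sc, sp]
  }
  total
}

#' Save a body model to a single JSON file
#'
#' The file carries a JSON header (format tag, tree, state counts, feature
#' settings, occlusion thresholds) plus the flattened weight vector and the
#' anchor offsets as base64-encoded little-endian doubles.
#'
#' @param model A [body_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  beta <- model_beta(model)
  anchors <- unlist(lapply(setdiff(model$tree$order, model$tree$root),
                           function(ch) as.vector(model$anchor[[ch]])))
  obj <- list(
    format = "babydpm-model",
    version = model$version,
    parts = model$tree$parts,
    parent = as.list(ifelse(is.na(model$tree$parent), "", model$tree$parent)),
    states = as.list(model$states),
    config = model$config,
    omega_score = as.list(model$omega_score),
    n_beta = length(beta),
    n_anchor = length(anchors),
    beta_b64 = jsonlite::base64_enc(writeBin(beta, raw(), size = 8L, endian = "little")),
    anchor_b64 = jsonlite::base64_enc(writeBin(anchors, raw(), size = 8L, endian = "little"))
  )
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' Load a body model saved by [save_model()]
#'
#' @param path Path to a model file.
#' @return A [body_model()].
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  obj <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e) stop("not a readable model file: ",
                                           conditionMessage(e)))
  if (!identical(obj$format, "babydpm-model"))
    stop("format error: missing babydpm-model header")
  if (!identical(obj$version, MODEL_VERSION))
    stop("format error: model version ", obj$version %||% "<missing>",
         " not supported (expected ", MODEL_VERSION, ")")
  parts <- obj$parts
  parent <- vapply(parts, function(p) {
    v <- obj$parent[[p]]
    if (is.null(v) || !nzchar(v)) NA_character_ else v
  }, character(1L))
  tree <- kinematic_tree(parts, parent)
  states <- vapply(parts, function(p) as.integer(obj$states[[p]]), integer(1L))
  cfg <- feature_config(cell_size_px = obj$config$cell_size_px,
                        bins = obj$config$bins,
                        normalize = obj$config$normalize,
                        interval = obj$config$interval,
                        min_level_px = obj$config$min_level_px,
                        patch_cells = obj$config$patch_cells,
                        train_scale = obj$config$train_scale %||% 1)
  model <- body_model(tree, states, cfg)
  beta_raw <- jsonlite::base64_dec(obj$beta_b64)
  if (length(beta_raw) != 8L * obj$n_beta)
    stop("format error: truncated weight payload")
  beta <- readBin(beta_raw, "double", n = obj$n_beta, size = 8L, endian = "little")
  if (length(beta) != beta_layout(model)$length)
    stop("format error: weight payload does not match declared shapes")
  model <- model_set_beta(model, beta)
  anc_raw <- jsonlite::base64_dec(obj$anchor_b64)
  if (length(anc_raw) != 8L * obj$n_anchor)
    stop("format error: truncated anchor payload")
  anc <- readBin(anc_raw, "double", n = obj$n_anchor, size = 8L, endian = "little")
  off <- 0L
  for (ch in setdiff(tree$order, tree$root)) {
    n <- length(model$anchor[[ch]])
    model$anchor[[ch]] <- array(anc[off + seq_len(n)], dim(model$anchor[[ch]]))
    off <- off + n
  }
  if (off != obj$n_anchor) stop("format error: anchor payload length mismatch")
  model$omega_score <- vapply(parts, function(p) {
    v <- obj$omega_score[[p]]
    if (is.null(v)) -Inf else as.numeric(v)
  }, numeric(1L))
  names(model$omega_score) <- parts
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
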