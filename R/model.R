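#' One-hot encode an amino-acid sequence
#'
#' Produces the network input: a `length x 21` matrix with one channel per
#' standard amino acid (alphabetical order `ACDEFGHIKLMNPQRSTVWY`) plus a 21st
#' channel for unknown/non-standard residues (`X`). Every row sums to 1.
#'
#' @param seq Amino-acid string.
#' @return Numeric matrix `nchar(seq) x 21`.
#' @export
encode_sequence <- function(seq) {
  if (!nzchar(seq)) stop("sequence is empty")
  aa <- strsplit(AA_ALPHABET, "")[[1]]
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, aa)
  idx[is.na(idx)] <- 21L
  m <- matrix(0, length(chars), 21)
  m[cbind(seq_along(chars), idx)] <- 1
  colnames(m) <- c(aa, "X")
  m
}

#' Scale raw surface areas to the unit interval
#'
#' Raw per-residue areas are capped at `cap` (100 Angstrom^2 by default, about
#' the 85th percentile of observed per-residue areas, so protruding residues
#' with disproportionate area do not dominate) and divided by `cap`, yielding
#' targets in `[0, 1]`.
#'
#' @param raw An `accessibility_profile` with `units = "raw_A2"`, or a numeric
#'   vector of areas.
#' @param cap Cap in Angstrom^2 (default 100).
#' @return Scaled profile (or numeric vector).
#' @export
preprocess_targets <- function(raw, cap = 100) {
  if (cap <= 0) stop("cap must be positive")
  if (inherits(raw, "accessibility_profile")) {
    out <- accessibility_profile(raw$position, pmin(raw$value, cap) / cap,
                                 residue = raw$residue, units = "scaled",
                                 id = attr(raw, "id"))
    return(out)
  }
  pmin(raw, cap) / cap
}

#' Training configuration for the accessibility predictor
#'
#' The architecture follows the published design: three stacked bidirectional
#' long short-term memory layers of 100, 64 and 32 units with rectified-linear
#' activations, and a linear output head; training minimises masked mean
#' squared error with Adam.
#'
#' @param layer_widths Hidden units per bidirectional layer.
#' @param activation `"relu"` (default) or `"tanh"` for cell/output
#'   activations; gates are always sigmoid.
#' @param epochs Training epochs (default 400).
#' @param learning_rate Adam step size (default 1e-3).
#' @param batch_size Minibatch size (default 16).
#' @param clipnorm Global gradient-norm clip (default 5; rectified-linear
#'   cells can otherwise overflow early in training).
#' @param seed Integer seed controlling initialisation and batch order.
#' @return List of class `model_config`.
#' @export
model_config <- function(layer_widths = c(100, 64, 32), activation = "relu",
                         epochs = 400, learning_rate = 1e-3, batch_size = 16,
                         clipnorm = 5, seed = 42) {
  stopifnot(all(layer_widths > 0), epochs >= 1, learning_rate > 0,
            batch_size >= 1)
  out <- list(layer_widths = as.integer(layer_widths), activation = activation,
              epochs = as.integer(epochs), learning_rate = learning_rate,
              batch_size = as.integer(batch_size), clipnorm = clipnorm,
              seed = as.integer(seed))
  class(out) <- "model_config"
  out
}

#' Assemble a training sample
#'
#' @param allele_name Allele the sequence belongs to.
#' @param sequence Amino-acid string in the mature-protein frame.
#' @param target Scaled accessibility profile (values in `[0, 1]`) whose
#'   positions index into `sequence`; positions without an observed area are
#'   simply absent and get masked out of the loss.
#' @param structure_id Identifier of the source structure.
#' @return List of class `training_sample` with `encoded`, `target`,
#'   `target_mask` vectors over the sequence length.
#' @export
training_sample <- function(allele_name, sequence, target, structure_id = "") {
  if (profile_units(target) != "scaled") {
    stop("target profile must be scaled to [0, 1]; see preprocess_targets()")
  }
  if (any(target$value < 0 | target$value > 1)) stop("target values outside [0, 1]")
  n <- nchar(sequence)
  if (any(target$position < 1 | target$position > n)) {
    stop("target positions outside the sequence")
  }
  y <- rep(0, n)
  m <- rep(0, n)
  y[target$position] <- target$value
  m[target$position] <- 1
  out <- list(allele_name = allele_name, structure_id = structure_id,
              sequence = sequence, encoded = encode_sequence(sequence),
              target = y, target_mask = m)
  class(out) <- "training_sample"
  out
}

pack_batch <- function(samples, max_len) {
  B <- length(samples)
  X <- array(0, c(B, max_len, 21))
  M <- matrix(0, B, max_len)
  Y <- matrix(0, B, max_len)
  W <- matrix(0, B, max_len)  # loss mask: valid AND observed
  for (i in seq_len(B)) {
    s <- samples[[i]]
    L <- nrow(s$encoded)
    X[i, 1:L, ] <- s$encoded
    M[i, 1:L] <- 1
    Y[i, 1:L] <- s$target
    W[i, 1:L] <- s$target_mask
  }
  list(X = X, M = M, Y = Y, W = W)
}

#' Train the bidirectional recurrent accessibility predictor
#'
#' Sequences are padded to the longest training length; padded positions are
#' carried through the recurrence unchanged and, together with positions
#' lacking an observed area, excluded from the loss. Training is fully
#' deterministic given `config$seed`.
#'
#' @param samples List of [training_sample()] objects.
#' @param config A [model_config()].
#' @param verbose Print the loss every 10 epochs.
#' @return Object of class `accessibility_model` carrying the weights, the
#'   config and the per-epoch loss trace.
#' @export
train_accessibility_model <- function(samples, config = model_config(),
                                      verbose = FALSE) {
  if (length(samples) == 0) stop("no training samples")
  if (all(vapply(samples, function(s) sum(s$target_mask), numeric(1)) == 0)) {
    stop("all target positions are masked")
  }
  max_len <- max(vapply(samples, function(s) nrow(s$encoded), integer(1)))
  with_seed(config$seed, {
    net <- list(layers = bilstm_init(21, config$layer_widths),
                Wout = glorot(2 * utils::tail(config$layer_widths, 1), 1),
                bout = 0,
                activation = config$activation)
    state <- adam_init(net_params(net))
    trace <- numeric(config$epochs)
    n <- length(samples)
    for (ep in seq_len(config$epochs)) {
      ord <- sample(n)
      losses <- c()
      for (start in seq(1, n, by = config$batch_size)) {
        ii <- ord[start:min(start + config$batch_size - 1, n)]
        batch <- pack_batch(samples[ii], max_len)
        lg <- net_loss_grad(batch$X, batch$M, batch$Y, net, W = batch$W)
        grads <- clip_global_norm(lg$grads, config$clipnorm)
        st <- adam_step(net_params(net), grads, state, config$learning_rate)
        net <- net_set_params(net, st$params)
        state <- st$state
        losses <- c(losses, lg$loss)
      }
      trace[ep] <- mean(losses)
      if (verbose && (ep %% 10 == 0 || ep == 1)) {
        message(sprintf("epoch %d loss %.5f", ep, trace[ep]))
      }
    }
    out <- list(net = net, config = config, loss_trace = trace,
                max_len = max_len)
    class(out) <- "accessibility_model"
    out
  })
}

#' @export
print.accessibility_model <- function(x, ...) {
  cat(sprintf("<accessibility_model> biLSTM %s, %d epochs, final loss %.5f\n",
              paste(x$config$layer_widths, collapse = "/"),
              x$config$epochs, utils::tail(x$loss_trace, 1)))
  invisible(x)
}

#' Predict per-position accessibility for an allele
#'
#' @param model A trained `accessibility_model`.
#' @param allele An [allele_sequence()], or a plain amino-acid string.
#' @param clip Clip predictions into `[0, 1]` (default TRUE; the linear head
#'   may slightly overshoot the target range).
#' @return A scaled `accessibility_profile` over positions `1..nchar(seq)`.
#' @export
predict_accessibility <- function(model, allele, clip = TRUE) {
  seq <- if (inherits(allele, "allele_sequence")) allele$sequence else allele
  id <- if (inherits(allele, "allele_sequence")) allele$allele_name else ""
  L <- nchar(seq)
  if (L > model$max_len) {
    stop("sequence longer (", L, ") than the trained maximum (", model$max_len, ")")
  }
  X <- array(0, c(1, L, 21))
  X[1, , ] <- encode_sequence(seq)
  M <- matrix(1, 1, L)
  fw <- net_forward(X, M, model$net)
  v <- as.vector(fw$yhat)
  if (clip) v <- pmin(pmax(v, 0), 1)
  accessibility_profile(seq_len(L), v, residue = strsplit(seq, "")[[1]],
                        units = "scaled", id = id)
}

#' Predict profiles for a set of alleles
#'
#' @param model A trained `accessibility_model`.
#' @param alleles Named list of [allele_sequence()] records.
#' @param clip Clip predictions into `[0, 1]`.
#' @return Named list of `accessibility_profile`s, position-aligned when the
#'   sequences share a frame.
#' @export
predict_profiles <- function(model, alleles, clip = TRUE) {
  lapply(alleles, function(a) predict_accessibility(model, a, clip = clip))
}

#' Mean-center an accessibility profile
#'
#' Subtracts the profile mean, as done before cross-predictor comparisons so
#' that systematic offsets between predictors do not dominate squared errors.
#'
#' @param profile An `accessibility_profile`.
#' @return Profile with mean-zero values (units preserved).
#' @export
mean_center <- function(profile) {
  out <- profile
  out$value <- profile$value - mean(profile$value)
  out
}

#' Position-specific squared error and MSE between two profiles
#'
#' `SE_i = (a_i - b_i)^2` over shared positions and their mean. Center both
#' profiles with [mean_center()] first when comparing predictors with
#' different baselines.
#'
#' @param a,b Accessibility profiles on a common positional frame.
#' @return List with `se` (data frame position/se) and `mse` (scalar).
#' @export
pairwise_se_mse <- function(a, b) {
  p <- paired_values(a, b)
  se <- (p$a - p$b)^2
  list(se = data.frame(position = p$position, se = se), mse = mean(se))
}

#' Classify positions as accessible by mean exceedance
#'
#' A position counts as accessible when its score strictly exceeds the
#' profile's own mean — each predictor is compared against its own baseline.
#' On a constant profile no position is accessible.
#'
#' @param profile An `accessibility_profile`.
#' @return Logical vector along the profile's positions.
#' @export
classify_accessible <- function(profile) {
  if (nrow(profile) == 0) stop("empty profile")
  profile$value > mean(profile$value)
}

#' Parse a third-party accessibility profile from TSV
#'
#' Reads `position`, `residue`, `score` columns. PaleAle-style files report
#' relative accessibility in percent and are divided by 100; NetSurfP-style
#' files are already in `[0, 1]` and taken as-is. When an allele sequence is
#' supplied, the residue column is cross-checked and mismatching positions
#' reported as a warning.
#'
#' @param path TSV file with columns `position`, `residue`, `score`.
#' @param dialect `"netsurfp_like"` or `"paleale_like"`.
#' @param allele Optional [allele_sequence()] for the residue cross-check.
#' @return A scaled `accessibility_profile`.
#' @export
parse_reference_profile <- function(path, dialect = c("netsurfp_like", "paleale_like"),
                                    allele = NULL) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  if (length(lines) < 2) stop("no data rows in ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("position", "residue", "score")
  if (!all(need %in% header)) {
    stop("expected columns position/residue/score in ", path)
  }
  rows <- lapply(seq.int(2, length(lines)), function(ln) {
    f <- strsplit(lines[ln], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(header)) stop("malformed row at line ", ln, " of ", path)
    v <- stats::setNames(f, header)
    pos <- suppressWarnings(as.integer(v["position"]))
    score <- suppressWarnings(as.numeric(v["score"]))
    if (is.na(pos) || is.na(score)) stop("malformed row at line ", ln, " of ", path)
    data.frame(position = pos, residue = v[["residue"]], score = score,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (dialect == "paleale_like") df$score <- df$score / 100
  if (!is.null(allele)) {
    expected <- substring(allele$sequence, df$position, df$position)
    bad <- df$position[expected != df$residue]
    if (length(bad) > 0) {
      warning("residue mismatch vs ", allele$allele_name, " at position(s) ",
              paste(bad, collapse = ", "))
    }
  }
  accessibility_profile(df$position, df$score, residue = df$residue,
                        units = "scaled", id = basename(path))
}
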