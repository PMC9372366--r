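test_that("one-hot encoding places residues in their channels", {
  e <- encode_sequence("A")
  expect_equal(dim(e), c(1, 21))
  expect_equal(unname(e[1, "A"]), 1)
  e2 <- encode_sequence("AX")
  expect_equal(unname(e2[2, 21]), 1)
  # unknown letters also route to channel 21; every row sums to exactly 1
  set.seed(2)
  seq <- paste(sample(c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B"),
                      50, replace = TRUE), collapse = "")
  expect_true(all(rowSums(encode_sequence(seq)) == 1))
  expect_error(encode_sequence(""), "empty")
})

test_that("target preprocessing caps at 100 and scales to [0, 1]", {
  expect_equal(preprocess_targets(150), 1.0)
  expect_equal(preprocess_targets(50), 0.5)
  expect_equal(preprocess_targets(0), 0.0)
  expect_error(preprocess_targets(50, cap = 0), "positive")
  prof <- toy_profile(c(150, 50, 0), units = "raw_A2")
  scaled <- preprocess_targets(prof)
  expect_equal(scaled$value, c(1, 0.5, 0))
  expect_equal(attr(scaled, "units"), "scaled")
})

test_that("mean-centering zeroes the profile mean", {
  expect_equal(mean_center(toy_profile(c(0.2, 0.4, 0.6)))$value, c(-0.2, 0, 0.2))
  expect_equal(mean_center(toy_profile(rep(0.3, 5)))$value, rep(0, 5))
  set.seed(3)
  p <- toy_profile(runif(40))
  expect_lt(abs(sum(mean_center(p)$value)), 1e-12)
})

test_that("pairwise SE/MSE follow their definitions and are symmetric", {
  a <- toy_profile(c(0.5, 0.2))
  b <- toy_profile(c(0.4, 0.3))
  r <- pairwise_se_mse(a, b)
  expect_equal(r$se$se, c(0.01, 0.01))
  expect_equal(r$mse, 0.01)
  expect_equal(pairwise_se_mse(b, a)$mse, r$mse)
  expect_equal(pairwise_se_mse(a, a)$mse, 0)
})

test_that("mean-exceedance classification is strict", {
  expect_equal(classify_accessible(toy_profile(c(0.2, 0.4, 0.9))),
               c(FALSE, FALSE, TRUE))
  expect_false(any(classify_accessible(toy_profile(rep(0.7, 4)))))
  set.seed(4)
  for (k in 1:5) {
    v <- runif(10)
    if (length(unique(v)) > 1) expect_true(any(classify_accessible(toy_profile(v))))
  }
})

test_that("reference profiles parse per dialect with residue cross-checks", {
  dir <- tempfile(); dir.create(dir)
  pale <- file.path(dir, "pale.tsv")
  writeLines(c("position\tresidue\tscore", "1\tA\t85", "2\tC\t10"), pale)
  p <- parse_reference_profile(pale, "paleale_like")
  expect_equal(p$value, c(0.85, 0.10))
  net <- file.path(dir, "net.tsv")
  writeLines(c("position\tresidue\tscore", "1\tA\t0.85", "2\tC\t0.10"), net)
  expect_equal(parse_reference_profile(net, "netsurfp_like")$value, c(0.85, 0.10))

  allele <- allele_sequence("A*90:01", "HLA00001", "AD")
  expect_warning(parse_reference_profile(net, "netsurfp_like", allele = allele),
                 "position\\(s\\) 2")

  bad <- file.path(dir, "bad.tsv")
  writeLines(c("position\tresidue\tscore", "1\tA\t0.85", "oops"), bad)
  expect_error(parse_reference_profile(bad, "netsurfp_like"), "line 3")
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  B <- 2; L <- 4; D <- 3
  X <- array(runif(B * L * D), c(B, L, D))
  M <- matrix(1, B, L); M[2, 4] <- 0
  W <- M; W[1, 2] <- 0
  Y <- matrix(runif(B * L), B, L)
  eps <- 1e-6
  for (actk in c("relu", "tanh")) {
    net <- snowflake:::net_set_params(
      list(activation = actk),
      list(layers = snowflake:::bilstm_init(D, c(3, 2)),
           Wout = snowflake:::glorot(4, 1), bout = 0.05))
    lg <- snowflake:::net_loss_grad(X, M, Y, net, W = W)
    check <- function(get, set, gana) {
      p <- get(net)
      for (i in sample(length(p), min(5, length(p)))) {
        n1 <- net; n2 <- net
        p1 <- p; p1[i] <- p1[i] + eps; n1 <- set(n1, p1)
        p2 <- p; p2[i] <- p2[i] - eps; n2 <- set(n2, p2)
        num <- (snowflake:::net_loss_grad(X, M, Y, n1, W = W)$loss -
                  snowflake:::net_loss_grad(X, M, Y, n2, W = W)$loss) / (2 * eps)
        expect_lt(abs(num - gana[i]) / max(abs(num), 1e-6), 1e-3)
      }
    }
    check(function(n) n$layers[[1]]$fwd$Wx,
          function(n, p) { n$layers[[1]]$fwd$Wx[] <- p; n },
          lg$grads$layers[[1]]$fwd$Wx)
    check(function(n) n$layers[[2]]$bwd$Wh,
          function(n, p) { n$layers[[2]]$bwd$Wh[] <- p; n },
          lg$grads$layers[[2]]$bwd$Wh)
    check(function(n) n$Wout, function(n, p) { n$Wout[] <- p; n }, lg$grads$Wout)
  }
})

rule_family_samples <- function(fam, gt, idx) {
  lapply(names(fam$alleles)[idx], function(nm) {
    training_sample(nm, fam$alleles[[nm]]$sequence, gt[[nm]])
  })
}

test_that("training fits a constant target and is seed-reproducible", {
  fam <- make_allele_family(base_length = 24, n_alleles = 6, n_polymorphic = 3,
                            seed = 5)
  samples <- lapply(fam$alleles, function(a) {
    training_sample(a$allele_name, a$sequence,
                    toy_profile(rep(0.5, nchar(a$sequence)), id = a$allele_name))
  })
  cfg <- model_config(layer_widths = c(8, 6), epochs = 60,
                      learning_rate = 0.01, batch_size = 4, seed = 1)
  m <- train_accessibility_model(samples, cfg)
  expect_lt(tail(m$loss_trace, 1), head(m$loss_trace, 1))
  p <- predict_accessibility(m, fam$alleles[[1]])
  expect_true(all(abs(p$value - 0.5) < 0.02))
  m2 <- train_accessibility_model(samples, cfg)
  expect_equal(m$loss_trace, m2$loss_trace, tolerance = 1e-6)
})

test_that("the network recovers a local context rule on held-out alleles", {
  fam <- make_allele_family(base_length = 40, n_alleles = 14, n_polymorphic = 6,
                            seed = 8)
  gt <- make_ground_truth_profiles(fam, rule_seed = 17)
  m <- train_accessibility_model(
    rule_family_samples(fam, gt, 1:11),
    model_config(layer_widths = c(24, 16), epochs = 150, learning_rate = 0.01,
                 batch_size = 4, seed = 2))
  held <- 12:14
  preds <- predict_profiles(m, fam$alleles[held])
  pv <- unlist(lapply(preds, function(p) p$value))
  gv <- unlist(lapply(gt[held], function(g) g$value))
  expect_lt(mean((pv - gv)^2), 0.02)
  expect_gt(stats::cor(pv, gv), 0.9)
  # raw (unclipped) predictions stay near the target range
  raw <- unlist(lapply(predict_profiles(m, fam$alleles[held], clip = FALSE),
                       function(p) p$value))
  expect_gt(mean(raw > -0.1 & raw < 1.1), 0.95)
})

test_that("masked positions are excluded from the loss and predictions stay allele-specific", {
  fam <- make_allele_family(base_length = 20, n_alleles = 4, n_polymorphic = 2,
                            seed = 6)
  a <- fam$alleles[[1]]
  # observe only half of the positions
  part <- toy_profile(rep(0.8, 10), positions = seq(1, 20, by = 2),
                      id = a$allele_name)
  s <- training_sample(a$allele_name, a$sequence, part)
  expect_equal(sum(s$target_mask), 10)
  m <- train_accessibility_model(list(s),
                                 model_config(layer_widths = c(6), epochs = 30,
                                              learning_rate = 0.02,
                                              batch_size = 1, seed = 3))
  expect_lt(tail(m$loss_trace, 1), 0.05)

  # alleles differing at a polymorphic position are not forced to identical
  # profiles
  gt <- make_ground_truth_profiles(fam, rule_seed = 23)
  m2 <- train_accessibility_model(rule_family_samples(fam, gt, 1:4),
                                  model_config(layer_widths = c(12), epochs = 80,
                                               learning_rate = 0.01,
                                               batch_size = 2, seed = 4))
  diffpair <- NULL
  nm <- names(fam$alleles)
  for (i in 1:3) for (j in (i + 1):4) {
    if (fam$alleles[[i]]$sequence != fam$alleles[[j]]$sequence) diffpair <- c(i, j)
  }
  if (!is.null(diffpair)) {
    pi_ <- predict_accessibility(m2, fam$alleles[[diffpair[1]]])
    pj <- predict_accessibility(m2, fam$alleles[[diffpair[2]]])
    expect_gt(max(abs(pi_$value - pj$value)), 0)
    expect_equal(pi_$position, pj$position)  # batch frame alignment
  }

  # sequence longer than the trained maximum is rejected
  expect_error(predict_accessibility(m2, strrep("A", 100)), "longer")
  # all-masked training data is rejected
  empty <- s; empty$target_mask[] <- 0
  expect_error(train_accessibility_model(list(empty),
                                         model_config(layer_widths = c(4),
                                                      epochs = 1)),
               "masked")
})

test_that("training trace depends only on data and seed, not on sample copies", {
  fam <- make_allele_family(base_length = 16, n_alleles = 3, n_polymorphic = 2,
                            seed = 9)
  a <- fam$alleles[[1]]
  target <- toy_profile(rep(c(0.2, 0.9), 8), id = a$allele_name)
  s <- training_sample(a$allele_name, a$sequence, target)
  cfg <- model_config(layer_widths = c(8), epochs = 80, learning_rate = 0.01,
                      batch_size = 2, seed = 5)
  m1 <- train_accessibility_model(list(s), cfg)
  m2 <- train_accessibility_model(list(s, s), cfg)
  p1 <- predict_accessibility(m1, a)
  p2 <- predict_accessibility(m2, a)
  expect_lt(max(abs(p1$value - p2$value)), 0.05)
})
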