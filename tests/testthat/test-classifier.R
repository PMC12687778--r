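# direct triple-loop convolution oracle
naive_conv3d <- function(x, W, b, cin, cout, k, stride, pad, in_dim) {
  out_dim <- floor((in_dim + 2 * pad - k) / stride) + 1
  xa <- array(0, c(cin, in_dim))
  for (c in seq_len(cin)) xa[c, , , ] <- array(x[c, ], in_dim)
  out <- array(0, c(cout, out_dim))
  for (o1 in seq_len(out_dim[1])) for (o2 in seq_len(out_dim[2])) {
    for (o3 in seq_len(out_dim[3])) {
      acc <- rep(0, cout)
      for (a in seq_len(k[1])) for (bb in seq_len(k[2])) {
        for (cc in seq_len(k[3])) {
          i1 <- (o1 - 1) * stride[1] + a - pad[1]
          i2 <- (o2 - 1) * stride[2] + bb - pad[2]
          i3 <- (o3 - 1) * stride[3] + cc - pad[3]
          if (i1 < 1 || i1 > in_dim[1] || i2 < 1 || i2 > in_dim[2] ||
              i3 < 1 || i3 > in_dim[3]) next
          kk <- a + (bb - 1) * k[1] + (cc - 1) * k[1] * k[2]
          for (co in seq_len(cout)) {
            for (ci in seq_len(cin)) {
              acc[co] <- acc[co] +
                W[co, ci + (kk - 1) * cin] * xa[ci, i1, i2, i3]
            }
          }
        }
      }
      out[, o1, o2, o3] <- acc + b
    }
  }
  matrix(out, nrow = cout)
}

test_that("the GEMM convolution matches a direct triple-loop oracle", {
  set.seed(99)
  in_dim <- c(6L, 5L, 4L)
  ly <- salnet:::new_conv(2L, 3L, c(3L, 3L, 3L), c(2L, 1L, 2L),
                          c(1L, 1L, 1L), in_dim)
  x <- matrix(rnorm(2 * prod(in_dim)), nrow = 2)
  got <- salnet:::conv_forward(x, ly, 1L)$out
  want <- naive_conv3d(x, ly$W, ly$b, 2L, 3L, ly$k, ly$stride, ly$pad,
                       in_dim)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("backpropagated gradients match finite differences for every head", {
  set.seed(5)
  B <- 3
  y <- c(0, 1, 1)
  for (head in c("softmax", "tanh", "sigmoid")) {
    cfg <- model_config(depth_preset = "small", width_scale = 0.5,
                        head = head, seed = 3)
    m <- build_classifier(cfg, 12)
    x <- matrix(rnorm(12^3 * B), nrow = 1)
    fw <- salnet:::net_forward(m, x, B)
    hl <- salnet:::head_loss(head, fw$out, y)
    bw <- salnet:::net_backward(m, hl$dz, fw$caches, B)
    g <- salnet:::collect_grads(m, bw$grads)
    p <- salnet:::collect_params(m)
    lossfn <- function(pp) {
      mm <- salnet:::assign_params(m, pp)
      salnet:::head_loss(head,
                         salnet:::net_forward(mm, x, B, FALSE)$out, y)$loss
    }
    for (nm in sample(names(p), 4)) {
      i <- sample(length(p[[nm]]), 1)
      eps <- 1e-5
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (lossfn(p1) - lossfn(p2)) / (2 * eps)
      expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
    }
    # input gradient (the saliency path)
    i <- 500
    eps <- 1e-5
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    fd <- (salnet:::head_loss(head,
                              salnet:::net_forward(m, x1, B, FALSE)$out,
                              y)$loss -
           salnet:::head_loss(head,
                              salnet:::net_forward(m, x2, B, FALSE)$out,
                              y)$loss) / (2 * eps)
    expect_equal(bw$dX[i], fd, tolerance = 1e-4)
  }
})

test_that("builds are seeded and parameter counts scale with width", {
  cfg <- model_config(depth_preset = "small", width_scale = 1, seed = 11)
  m1 <- build_classifier(cfg, 24)
  m2 <- build_classifier(cfg, 24)
  expect_identical(salnet:::collect_params(m1), salnet:::collect_params(m2))
  m3 <- build_classifier(model_config(depth_preset = "small",
                                      width_scale = 1, seed = 12), 24)
  expect_false(identical(salnet:::collect_params(m1),
                         salnet:::collect_params(m3)))

  # quartering the width quarters both channel counts of interior convs,
  # so their weight counts shrink by ~ 0.25^2
  q <- build_classifier(model_config(depth_preset = "small",
                                     width_scale = 0.25, seed = 11), 24)
  pf <- salnet:::collect_params(m1)
  pq <- salnet:::collect_params(q)
  conv_w <- grep("^L[34]\\.c[12]\\.W$", names(pf), value = TRUE)
  for (nm in conv_w) {
    expect_equal(length(pq[[nm]]) / length(pf[[nm]]), 0.25^2)
  }
  expect_true(n_parameters(q) < n_parameters(m1))

  # the 50-layer bottleneck plan builds and counts deterministically
  r50 <- model_config(depth_preset = "resnet50", width_scale = 0.0625,
                      seed = 2)
  ma <- build_classifier(r50, 32)
  expect_equal(n_parameters(ma), n_parameters(build_classifier(r50, 32)))
  expect_equal(sum(vapply(ma$layers, function(l)
    identical(l$type, "block"), logical(1))), 16)  # 3 + 4 + 6 + 3
})

test_that("a feature head yields feature vectors of the requested width", {
  cfg <- model_config(depth_preset = "small", width_scale = 0.5,
                      head = "feature", feature_dim = 64, seed = 1)
  m <- build_classifier(cfg, 12)
  v <- brain_volume(array(runif(12^3), dim = rep(12, 3)))
  f <- predict(m, list(a = v), type = "feature")
  expect_equal(dim(f), c(1L, 64L))
  expect_error(model_config(head = "feature"), class = "salnet_value_error")
  expect_error(model_config(head = "softmax", feature_dim = 8),
               class = "salnet_value_error")
})

test_that("undersized inputs are rejected with a sizing error", {
  expect_error(build_classifier(model_config(depth_preset = "small"), 4),
               class = "salnet_sizing_error")
  expect_error(build_classifier(model_config(depth_preset = "resnet50"), 16),
               class = "salnet_sizing_error")
})

test_that("the training protocol rejects controls and leaky or one-sided splits", {
  co <- shared_cohort()
  rec <- co$records
  ctrl <- rec$subject_id[rec$group == "control"][1]
  his <- rec$subject_id[rec$group == "high"]
  los <- rec$subject_id[rec$group == "low"]
  expect_error(train_spec(c(his[1:3], los[1:3]), c(his[3], los[4])),
               class = "salnet_protocol_error")
  m <- build_classifier(model_config(depth_preset = "small",
                                     width_scale = 0.25), 32)
  spec_ctrl <- train_spec(c(his[1:3], los[1:3], ctrl),
                          c(his[4:5], los[4:5]), epochs = 1)
  expect_error(train_classifier(m, co$volumes, rec, spec_ctrl),
               class = "salnet_protocol_error")
  spec_onesided <- train_spec(his[1:6], c(his[7], los[1]), epochs = 1)
  expect_error(train_classifier(m, co$volumes, rec, spec_onesided),
               class = "salnet_protocol_error")
})

test_that("kNN hybrid decisions match a hand-enumerated majority vote", {
  # six labelled points and two queries in a 2D feature plane
  m <- probe_feature_model()
  train <- list(
    a = vol_from_xy(0, 0), b = vol_from_xy(0, 1), c = vol_from_xy(1, 0),
    d = vol_from_xy(4, 4), e = vol_from_xy(4, 5), f = vol_from_xy(5, 4),
    q1 = vol_from_xy(0.6, 0.4), q2 = vol_from_xy(3.8, 4.2),
    q3 = vol_from_xy(4, 4)
  )
  rec <- data.frame(
    subject_id = names(train),
    group = c("low", "low", "low", "high", "high", "high",
              "high", "low", "low"),  # query truths irrelevant here
    stringsAsFactors = FALSE
  )
  spec <- train_spec(c("a", "b", "c", "d", "e", "f"), c("q1", "q2", "q3"),
                     epochs = 1)
  hk <- hybrid_classify(m, train, rec, spec, head = "knn", k = 3)
  pred <- hk$result$predictions
  # q1 is nearest a, b, c (all low); q2 nearest d, e, f (all high)
  expect_equal(pred$predicted[pred$subject_id == "q1"], "low")
  expect_equal(pred$predicted[pred$subject_id == "q2"], "high")
  # k = 1 with a query equal to a training point returns that point's label
  h1 <- hybrid_classify(m, train, rec, spec, head = "knn", k = 1)
  expect_equal(h1$result$predictions$predicted[3], "high")

  # the vote is invariant to the order of the training subjects
  spec_perm <- train_spec(c("f", "b", "d", "a", "e", "c"),
                          c("q1", "q2", "q3"), epochs = 1)
  hp <- hybrid_classify(m, train, rec, spec_perm, head = "knn", k = 3)
  expect_equal(hp$result$predictions$predicted,
               hk$result$predictions$predicted)

  # SVM separates the same toy clusters
  hs <- hybrid_classify(m, train, rec, spec, head = "svm")
  expect_equal(hs$result$predictions$predicted[1:2], c("low", "high"))

  expect_error(hybrid_classify(m, train, rec, spec, head = "knn", k = 4),
               class = "salnet_value_error")
  expect_error(hybrid_classify(m, train, rec, spec, head = "knn", k = 99),
               class = "salnet_value_error")
})

test_that("multi-restart fitting returns the best attempt and the accuracy distribution", {
  co <- shared_cohort()
  sp <- make_split(co$records, test_n = 4, seed = 3)
  spec <- train_spec(sp$train_ids, sp$test_ids, epochs = 2, seed = 3)
  fit <- severity_cnn(co$volumes, co$records, spec,
                      config = model_config(depth_preset = "small",
                                            width_scale = 0.25, seed = 40),
                      restarts = 2)
  expect_length(fit$restart_accuracies, 2)
  expect_equal(fit$result$accuracy, max(fit$restart_accuracies))
})

test_that("controls classification reports the fraction assigned low", {
  m <- probe_feature_model()
  train <- list(a = vol_from_xy(0, 0), b = vol_from_xy(0, 1),
                d = vol_from_xy(4, 4), e = vol_from_xy(4, 5))
  rec <- data.frame(subject_id = c("a", "b", "d", "e"),
                    group = c("low", "low", "high", "high"))
  spec <- train_spec(c("a", "b", "d", "e"), character(0), epochs = 1)
  hk <- structure(list(fit = m, head = "knn", k = 1,
                       train_features = predict(m, train, type = "feature"),
                       train_labels = factor(rec$group,
                                             levels = c("low", "high"))),
                  class = "hybrid_classifier")
  controls <- list(c1 = vol_from_xy(0.1, 0.1), c2 = vol_from_xy(0.2, 0.4),
                   c3 = vol_from_xy(4.1, 4.1))
  expect_equal(classify_controls(hk, controls), 2 / 3)
  expect_error(classify_controls(hk, list()), class = "salnet_value_error")
})
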