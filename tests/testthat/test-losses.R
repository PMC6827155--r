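test_that("ground-truth score maps fill boxes with scores and background with 0.05", {
  m0 <- build_gt_score_map(NULL, numeric(0), c(6, 6))
  expect_true(all(m0 == 0.05))

  m1 <- build_gt_score_map(c(2, 3, 5, 6), 1.0, c(10, 10))
  expect_true(all(m1[4:6, 3:5] == 1))
  expect_identical(sum(m1 == 1), 9L)
  expect_true(all(m1[m1 != 1] == 0.05))

  # overlap takes the maximum score regardless of box order
  boxes <- rbind(c(0, 0, 4, 4), c(2, 2, 6, 6))
  for (scores in list(c(0.3, 0.9), c(0.9, 0.3))) {
    m2 <- build_gt_score_map(boxes, scores, c(8, 8))
    expect_true(all(m2[3:4, 3:4] == 0.9))
  }
  expect_error(build_gt_score_map(c(0, 0, 9, 9), 0.5, c(5, 5)), "outside")
  expect_error(build_gt_score_map(c(0, 0, 2, 2), 1.5, c(5, 5)), "\\[0, 1\\]")
})

test_that("attention loss is the squared Frobenius norm, zero iff maps agree", {
  D <- build_gt_score_map(c(1, 1, 3, 3), 0.8, c(4, 4))
  expect_identical(attention_loss(D, D), 0)
  expect_identical(attention_loss(matrix(c(1, 0), 1, 2),
                                  matrix(0, 1, 2)), 1)
  set.seed(1)
  X <- matrix(runif(16), 4, 4); Y <- matrix(runif(16), 4, 4)
  expect_equal(attention_loss(X, Y), sum((X - Y)^2))
  expect_equal(attention_loss(X, Y, "mean"), mean((X - Y)^2))
  expect_gt(attention_loss(X, Y), 0)
  expect_error(attention_loss(X, matrix(0, 2, 2)), "shapes differ")
})

test_that("detection loss has the stated closed forms and zero at perfect predictions", {
  anchor <- c(10, 10, 20, 20)
  triple <- list(B = anchor, T = c(12, 11, 22, 21), R = 1)
  expect_equal(detection_loss(rbind(c(12, 11, 22, 21)), 1, list(triple)), 0,
               tolerance = 1e-9)

  # one coordinate offset error of exactly 1 under smooth-L1 contributes 0.5
  t_target <- maScreen:::encode_box(triple$T, anchor)
  t_off <- t_target + c(1, 0, 0, 0)
  # decode dx offset of +1: centre shifted by anchor width
  pred <- triple$T + c(10, 0, 10, 0)
  expect_equal(detection_loss(rbind(pred), 1, list(triple)), 0.5,
               tolerance = 1e-9)

  # random batch matches a straight-line oracle
  set.seed(2)
  triples <- lapply(1:6, function(k) {
    B <- c(x0 <- runif(1, 0, 50), y0 <- runif(1, 0, 50), x0 + runif(1, 5, 20),
           y0 + runif(1, 5, 20))
    Tk <- B + runif(4, -2, 2)
    if (Tk[3] <= Tk[1]) Tk[3] <- Tk[1] + 1
    if (Tk[4] <= Tk[2]) Tk[4] <- Tk[2] + 1
    list(B = B, T = Tk, R = sample(0:1, 1))
  })
  preds <- t(vapply(triples, function(tr) tr$T + runif(4, -1, 1), numeric(4)))
  scores <- runif(6, 0.05, 0.95)
  sl1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)
  enc <- function(b, a) c(((b[1] + b[3]) / 2 - (a[1] + a[3]) / 2) / (a[3] - a[1]),
                          ((b[2] + b[4]) / 2 - (a[2] + a[4]) / 2) / (a[4] - a[2]),
                          log((b[3] - b[1]) / (a[3] - a[1])),
                          log((b[4] - b[2]) / (a[4] - a[2])))
  ref <- mean(vapply(1:6, function(k)
    sum(sl1(enc(preds[k, ], triples[[k]]$B) -
            enc(triples[[k]]$T, triples[[k]]$B))), numeric(1))) +
    mean(vapply(1:6, function(k)
      -(triples[[k]]$R * log(scores[k]) +
          (1 - triples[[k]]$R) * log(1 - scores[k])), numeric(1)))
  expect_equal(detection_loss(preds, scores, triples), ref)
  expect_error(detection_loss(NULL, numeric(0), list()), "no training triples")
})

test_that("total loss combines terms linearly in lambda", {
  expect_identical(total_loss(1.5, 2, 0), 1.5)
  expect_identical(total_loss(1, 2, 0.5), 2)
  # monotone nondecreasing in lambda for positive attention loss
  ls <- vapply(seq(0, 2, 0.25), function(l) total_loss(1, 0.7, l), numeric(1))
  expect_true(all(diff(ls) >= 0))
  # gradient w.r.t. the attention input scales linearly with lambda
  D <- matrix(0.05, 4, 4); X <- matrix(0.2, 4, 4)
  eps <- 1e-6
  g_at <- function(lambda) {
    Xp <- X; Xp[1, 1] <- Xp[1, 1] + eps
    (total_loss(0, attention_loss(Xp, D), lambda) -
       total_loss(0, attention_loss(X, D), lambda)) / eps
  }
  expect_equal(g_at(2) / g_at(1), 2, tolerance = 1e-6)
})

test_that("gradient descent on a two-lesion scene decreases the composite loss", {
  # seeded scene: two target boxes; learn box offsets, objectness logits,
  # and the predicted score map jointly by plain gradient descent
  set.seed(42)
  anchors <- list(c(8, 8, 24, 24), c(30, 34, 44, 48))
  targets <- list(c(10, 9, 26, 23), c(28, 33, 42, 47))
  triples <- lapply(1:2, function(k) list(B = anchors[[k]], T = targets[[k]],
                                          R = 1))
  D <- build_gt_score_map(round(rbind(targets[[1]], targets[[2]]) / 4),
                          c(0.9, 0.9), c(16, 16))

  theta <- list(t = matrix(rnorm(8, 0, 0.4), 2, 4),   # predicted offsets
                logit = c(-1, -0.5),
                X = matrix(0, 16, 16))
  decode <- function(t, a) {
    aw <- a[3] - a[1]; ah <- a[4] - a[2]
    cx <- (a[1] + a[3]) / 2 + t[1] * aw; cy <- (a[2] + a[4]) / 2 + t[2] * ah
    w <- aw * exp(t[3]); h <- ah * exp(t[4])
    c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  }
  loss_of <- function(th) {
    preds <- t(vapply(1:2, function(k) decode(th$t[k, ], anchors[[k]]),
                      numeric(4)))
    det <- detection_loss(preds, 1 / (1 + exp(-th$logit)), triples)
    total_loss(det, attention_loss(th$X, D), lambda = 0.1)
  }
  flat <- function(th) c(th$t, th$logit, th$X)
  unflat <- function(v) list(t = matrix(v[1:8], 2, 4), logit = v[9:10],
                             X = matrix(v[-(1:10)], 16, 16))
  losses <- numeric(51)
  losses[1] <- loss_of(theta)
  v <- flat(theta)
  for (it in 1:50) {
    g <- numeric(length(v))
    for (j in 1:10) {  # finite-difference grads for the 10 detector params
      vp <- v; vp[j] <- vp[j] + 1e-5
      g[j] <- (loss_of(unflat(vp)) - losses[it]) / 1e-5
    }
    th <- unflat(v)
    g[-(1:10)] <- 0.1 * 2 * (th$X - D)   # analytic attention-map gradient
    v <- v - 0.05 * g
    losses[it + 1] <- loss_of(unflat(v))
  }
  expect_lt(losses[51], losses[1] * 0.5)
  expect_true(all(diff(losses) < 1e-6))  # essentially monotone descent
})
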