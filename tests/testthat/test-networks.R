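ref_anatomy <- function() matrix(rep(0.05, 80), 4, 20)

test_that("zero-initialized networks produce the architecture-forced outputs", {
  ppn <- zero_params(init_network(network_descriptor("ppn")))
  expect_identical(ppn_forward(ppn, ref_anatomy(), c(80, 60, 55, 50)), 0.5)
  dpn <- zero_params(init_network(network_descriptor("dpn")))
  out <- dpn_forward(dpn, ref_anatomy(), 7)
  expect_identical(unname(out[, 1]), c(0, 0, 0, 0))
})

test_that("eval-mode forward passes are deterministic and bounded", {
  set.seed(20)
  ppn <- init_network(network_descriptor("ppn"))
  dpn <- init_network(network_descriptor("dpn"))
  A <- array(runif(4 * 20 * 7), c(4, 20, 7))
  tot <- matrix(runif(28, 30, 90), 4)
  p1 <- ppn_forward(ppn, A, tot)
  p2 <- ppn_forward(ppn, A, tot)
  expect_identical(p1, p2)
  expect_true(all(p1 > 0 & p1 < 1))
  rx <- runif(7, 5.5, 8)
  expect_identical(dpn_forward(dpn, A, rx), dpn_forward(dpn, A, rx))
  # train mode with dropout is stochastic
  set.seed(22); t1 <- ppn_forward(ppn, A, tot, mode = "train")
  set.seed(23); t2 <- ppn_forward(ppn, A, tot, mode = "train")
  expect_false(identical(t1, t2))
  # but reproducible under the same seed
  set.seed(22); t3 <- ppn_forward(ppn, A, tot, mode = "train")
  expect_identical(t1, t3)
})

test_that("backpropagation matches central finite differences", {
  ns <- asNamespace("brachynet")
  set.seed(42)
  for (head in c("ppn", "dpn")) {
    desc <- network_descriptor(head, channels = c(3L, 4L, 4L, 3L),
                               dense_width = 8L, dropout = 0)
    par <- init_network(desc, init_scale = 0.5)
    A <- array(runif(4 * 20 * 3), c(4, 20, 3))
    if (head == "ppn") {
      x0 <- ns$.ppn_x0(list(anat = A, total = matrix(runif(12, 40, 90), 4)), desc)
      target <- c(1, 0, 1)
      lossf <- function(q) ns$.ppn_loss_grad(q, x0, target, "eval")
    } else {
      x0 <- ns$.dpn_x0(list(anat = A, rx = c(7, 6, 8)), desc)
      target <- matrix(runif(12, 4, 9), 4)
      lossf <- function(q) ns$.dpn_loss_grad(q, x0, target, "eval")
    }
    lg <- lossf(par)
    expect_gte(lg$loss, 0)
    paths <- ns$.tensor_paths(par)
    eps <- 1e-6
    set.seed(9)
    for (nm in names(paths)) {
      tn <- ns$.get_tensor(par, paths[[nm]])
      for (i in sample(length(tn), min(3, length(tn)))) {
        p2 <- ns$.set_tensor(par, paths[[nm]], `[<-`(tn, i, tn[i] + eps))
        p3 <- ns$.set_tensor(par, paths[[nm]], `[<-`(tn, i, tn[i] - eps))
        fd <- (lossf(p2)$loss - lossf(p3)$loss) / (2 * eps)
        an <- ns$.get_tensor(lg$grads, paths[[nm]])[i]
        expect_equal(an, fd, tolerance = 1e-4)
      }
    }
  }
})

test_that("gradient of the dose loss at zero parameters is nonzero", {
  ns <- asNamespace("brachynet")
  desc <- network_descriptor("dpn", dropout = 0)
  par <- zero_params(init_network(desc))
  set.seed(30)
  A <- array(runif(4 * 20 * 2), c(4, 20, 2))
  x0 <- ns$.dpn_x0(list(anat = A, rx = c(7, 6)), desc)
  lg <- ns$.dpn_loss_grad(par, x0, matrix(7, 4, 2), "eval")
  # zero output vs nonzero target: the output-layer bias gradient must push
  g <- unlist(lg$grads)
  expect_gt(max(abs(g)), 0)
})

test_that("checkpoints round-trip bit-identically and verify integrity", {
  set.seed(24)
  ppn <- init_network(network_descriptor("ppn"))
  expect_equal(count_parameters(ppn), 100865L)
  path <- tempfile(fileext = ".json")
  save_checkpoint(ppn, path)
  back <- load_checkpoint(path)
  A <- ref_anatomy()
  expect_identical(ppn_forward(back, A, c(80, 60, 55, 50)),
                   ppn_forward(ppn, A, c(80, 60, 55, 50)))
  # descriptor mismatch rejected
  expect_error(load_checkpoint(path, network_descriptor("dpn")), "descriptor")
  # corruption detected: alter one serialized weight, keep the JSON valid
  txt <- readLines(path)
  txt <- sub("\"data\":\\[\"[-0-9.]", "\"data\":[\"5", txt)
  writeLines(txt, path)
  expect_error(load_checkpoint(path), "checksum")
})
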