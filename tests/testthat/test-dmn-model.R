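spec <- default_dmn()
constants <- load_constants()

test_that("edge typing follows the cortical hierarchy", {
  typ <- function(s, t) spec$edges$type[edge_index(spec, s, t)]
  expect_identical(typ("lLP", "mPFC"), "forward")
  expect_identical(typ("rLP", "mPFC"), "forward")
  expect_identical(typ("Prec", "mPFC"), "forward")
  expect_identical(typ("lLP", "Prec"), "forward")
  expect_identical(typ("mPFC", "lLP"), "backward")
  expect_identical(typ("mPFC", "Prec"), "backward")
  expect_identical(typ("Prec", "rLP"), "backward")
  expect_identical(typ("lLP", "rLP"), "lateral")
  expect_identical(typ("rLP", "lLP"), "lateral")
})

test_that("edge subsets partition by mPFC incidence", {
  fp <- spec$subsets$frontoparietal
  pa <- spec$subsets$parietal
  expect_length(fp, 6)
  expect_length(pa, 6)
  expect_identical(sort(c(fp, pa)), 1:12)
  inc <- spec$edges$source == "mPFC" | spec$edges$target == "mPFC"
  expect_identical(fp, which(inc))
  expect_identical(spec$subsets$full, 1:12)
})

test_that("network validation rejects malformed graphs", {
  nodes <- spec$nodes
  edges <- spec$edges
  expect_error(dmn_spec(nodes[1:3, ], edges), "4 nodes")
  expect_error(dmn_spec(nodes, edges[1:11, ]), "12 directed edges")
  bad <- edges
  bad$source[1] <- bad$target[1]
  expect_error(dmn_spec(nodes, bad), "[Ss]elf-edges")
  bad <- edges
  bad$type[1] <- "sideways"
  expect_error(dmn_spec(nodes, bad), "forward, backward or lateral")
  expect_error(dmn_spec(nodes, edges, subsets = list(odd = c(1L, 13L))),
               "invalid edge indices")
})

test_that("the origin is an exact equilibrium and the linearization is stable", {
  p <- dcm_params()
  x_star <- equilibrium(p, spec, constants)
  expect_identical(x_star, numeric(32))
  J <- jacobian(p, spec, constants = constants)
  expect_true(attr(J, "stable"))
  expect_lt(attr(J, "max_re"), 0)
  expect_identical(dim(J), c(32L, 32L))
})

test_that("the analytic state Jacobian matches finite differences", {
  p <- dcm_params(a = seq(-0.3, 0.25, length.out = 12),
                  intrinsic = matrix(seq(-0.1, 0.1, length.out = 32), 4, 8))
  m <- specdcm:::compile_model(p, spec, constants)
  x <- seq(-0.05, 0.08, length.out = 32)
  Ja <- specdcm:::erp_jac(x, m)
  h <- 1e-6
  Jn <- vapply(1:32, function(j) {
    xp <- x; xm <- x
    xp[j] <- xp[j] + h
    xm[j] <- xm[j] - h
    (specdcm:::erp_f(xp, m) - specdcm:::erp_f(xm, m)) / (2 * h)
  }, numeric(32))
  expect_lt(max(abs(Ja - Jn)), 1e-4)
})

test_that("transfer functions and predicted spectra are well formed", {
  p <- dcm_params()
  freqs <- default_freqs()
  expect_length(freqs, 117L)
  Tf <- transfer_functions(p, spec, freqs, constants)
  expect_identical(dim(Tf), c(4L, 4L, 117L))
  expect_true(all(is.finite(Re(Tf))))
  lead <- make_lead_field(8, seed = 1)
  pred <- predict_csd(p, spec, lead, freqs, constants)
  for (f in c(1L, 60L, 117L)) {
    G <- pred$csd[, , f]
    expect_lt(max(abs(G - Conj(t(G)))), 1e-12)
    ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(Re(ev)), 0)
  }
})

test_that("coupling parameters scale the compiled A-matrices multiplicatively", {
  i <- edge_index(spec, "lLP", "mPFC")
  a <- numeric(12)
  a[i] <- 0.4
  m0 <- specdcm:::compile_model(dcm_params(), spec, constants)
  m1 <- specdcm:::compile_model(dcm_params(a = a), spec, constants)
  src <- match("lLP", spec$nodes$name)
  tgt <- match("mPFC", spec$nodes$name)
  expect_equal(m1$AF[tgt, src], m0$AF[tgt, src] * exp(0.4))
  # other entries untouched
  m1$AF[tgt, src] <- m0$AF[tgt, src]
  expect_identical(m1$AF, m0$AF)
  expect_identical(m1$AB, m0$AB)
  expect_identical(m1$AL, m0$AL)
})

test_that("unstable parameterizations are refused with a clear error", {
  p <- dcm_params(a = rep(2.5, 12))
  lead <- make_lead_field(8, seed = 1)
  expect_error(predict_csd(p, spec, lead, default_freqs(), constants),
               "unstable linearization")
})

test_that("parameter vectorization round-trips and validates", {
  v <- seq(-0.2, 0.2, length.out = 58)
  p <- unvec_params(v)
  expect_identical(unname(vec_params(p)), v)
  expect_identical(names(vec_params(p))[1:12], paste0("a", 1:12))
  expect_error(dcm_params(a = numeric(11)), "12 entries")
  expect_error(unvec_params(numeric(57)))
  expect_error(dcm_params(a = c(NA, numeric(11))), "finite")
})
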