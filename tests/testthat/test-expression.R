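test_that("quantile normalization equalizes column distributions", {
  m <- matrix(c(1, 2, 3, 4), nrow = 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  out <- quantile_normalize(m)
  expect_equal(unname(out[, 1]), c(2, 3))
  expect_equal(unname(out[, 2]), c(2, 3))
  # identical columns are untouched
  m2 <- matrix(c(5, 1, 9, 5, 1, 9), nrow = 3,
               dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(quantile_normalize(m2), m2)
  # defining property: sorted columns identical; and idempotence
  set.seed(42)
  m3 <- matrix(2^rnorm(600, 8, 2), nrow = 100,
               dimnames = list(sprintf("g%03d", 1:100), paste0("s", 1:6)))
  n3 <- quantile_normalize(m3)
  ref <- sort(n3[, 1])
  for (j in 2:ncol(n3)) expect_equal(unname(sort(n3[, j])), unname(ref))
  expect_equal(quantile_normalize(n3), n3, tolerance = 1e-12)
  # row order preserved
  expect_equal(rownames(n3), rownames(m3))
})

test_that("ANOVA screen matches a direct F-statistic oracle", {
  set.seed(7)
  g <- rep(c("A", "B"), each = 3)
  lx <- c(rnorm(3, 0, 0.5), rnorm(3, 2, 0.5))
  m <- matrix(2^lx, nrow = 1, dimnames = list("g1", paste0("s", 1:6)))
  p <- anova_screen(m, g)
  oracle <- stats::oneway.test(lx ~ factor(g), var.equal = TRUE)$p.value
  expect_equal(unname(p), oracle, tolerance = 1e-12)
  # three groups, several genes, against aov
  g3 <- rep(c("A", "B", "C"), each = 3)
  lm3 <- matrix(rnorm(45, 5, 1), nrow = 5,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:9)))
  p3 <- anova_screen(2^lm3, g3)
  for (i in 1:5) {
    fit <- summary(stats::aov(lm3[i, ] ~ factor(g3)))[[1]]
    expect_equal(unname(p3[i]), fit[["Pr(>F)"]][1], tolerance = 1e-10)
  }
})

test_that("ANOVA conventions: identical samples and label permutations", {
  m <- matrix(4, nrow = 2, ncol = 6,
              dimnames = list(c("g1", "g2"), paste0("s", 1:6)))
  g <- rep(c("A", "B"), each = 3)
  expect_equal(unname(anova_screen(m, g)), c(1, 1))
  # zero variance with different means is certain regulation
  m2 <- matrix(c(rep(2, 3), rep(8, 3)), nrow = 1, byrow = TRUE,
               dimnames = list("g1", paste0("s", 1:6)))
  expect_equal(unname(anova_screen(m2, g)), 0)
  # permuting samples within groups changes nothing
  set.seed(11)
  m3 <- matrix(2^rnorm(60, 8, 1), nrow = 10,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:6)))
  perm <- c(3, 1, 2, 6, 5, 4)  # within-group shuffle
  expect_equal(anova_screen(m3, g), anova_screen(m3[, perm], g[perm]))
})

test_that("regulated-gene selection applies both cut-offs strictly", {
  d <- data.frame(gene = c("up", "weak_fc", "weak_p"),
                  log2fc = c(log2(2.1), log2(1.9), 3),
                  p_value = c(0.001, 1e-6, 0.01))
  expect_equal(select_regulated(d), "up")
  expect_error(select_regulated(d, fc_threshold = 0), "positive")
})

test_that("type-I error of the selection pipeline matches the nominal level", {
  set.seed(1)
  n_genes <- 1000
  g <- rep(c("A", "B"), each = 3)
  lmat <- matrix(rnorm(n_genes * 6, 8, 0.5), nrow = n_genes,
                 dimnames = list(sprintf("g%04d", 1:n_genes),
                                 paste0("s", 1:6)))
  x <- expression_matrix(2^lmat, g)
  d <- diff_expression(x, group_a = "A", group_b = "B")
  n_sel <- length(select_regulated(d))
  bounds <- stats::qbinom(c(0.005, 0.995), n_genes, 0.005)
  expect_gte(n_sel, bounds[1])
  expect_lte(n_sel, bounds[2])
})

test_that("sample PCA separates duplicated clusters and orders variance", {
  base_a <- rnorm(50, 8, 2)
  base_b <- base_a + c(rep(2, 25), rep(-2, 25))
  lmat <- cbind(a1 = base_a, a2 = base_a, b1 = base_b, b2 = base_b)
  rownames(lmat) <- paste0("g", 1:50)
  pc <- pca_samples(2^lmat)
  # rank-1 structure: one component explains everything
  expect_equal(pc$explained[1], 1, tolerance = 1e-9)
  expect_equal(pc$scores["a1", 1], pc$scores["a2", 1], tolerance = 1e-9)
  expect_gt(abs(pc$scores["a1", 1] - pc$scores["b1", 1]), 1)
  # eigenvalue oracle on a small matrix
  set.seed(3)
  lm4 <- matrix(rnorm(12), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  pc4 <- pca_samples(2^lm4)
  centered <- scale(t(lm4), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(centered), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(pc4$explained, ev / sum(ev), tolerance = 1e-9)
  expect_true(all(diff(pc4$explained) <= 1e-12))
  # constant matrix: zero variance handled with empty loadings
  const <- matrix(4, 3, 3, dimnames = list(paste0("g", 1:3),
                                           paste0("s", 1:3)))
  expect_length(pca_samples(const)$explained, 0L)
})

test_that("GPR rules project gene changes onto reactions", {
  mets <- list(metabolite("a", carbon_atoms = 1),
               metabolite("b", carbon_atoms = 1))
  rxns <- list(
    reaction("single", c(a = -1, b = 1), 0, 1, gpr = "g1"),
    reaction("complex", c(a = -1, b = 1), 0, 1, gpr = "g2 and g3"),
    reaction("isozymes", c(a = -1, b = 1), 0, 1, gpr = "g4 or g5"),
    reaction("nogpr", c(a = -1, b = 1), 0, 1))
  m <- metabolic_model(mets, rxns, metadata = list(name = "t", version = "1"))
  fc <- c(g1 = 0.7, g2 = 2, g3 = 0.1, g4 = 1, g5 = -2)
  sig <- c(g1 = TRUE, g2 = TRUE, g3 = FALSE, g4 = TRUE, g5 = TRUE)
  tab <- reaction_expression_change(m, fc, sig)
  get <- function(id, col) tab[tab$reaction_id == id, col]
  expect_equal(get("single", "d_expression"), 0.7)
  expect_true(get("single", "significant"))
  # complex: the limiting (smallest |change|) subunit wins
  expect_equal(get("complex", "d_expression"), 0.1)
  expect_false(get("complex", "significant"))
  # isozymes: the extreme signed change wins, flagged on sign disagreement
  expect_equal(get("isozymes", "d_expression"), -2)
  expect_true(get("isozymes", "ambiguous_sign"))
  expect_false(get("nogpr", "has_evidence"))
  # unmapped genes are ignored with a warning
  expect_warning(reaction_expression_change(m, fc[-1], sig[-1]),
                 "without expression values")
})
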