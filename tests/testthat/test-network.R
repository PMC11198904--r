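# Strong-pair filtering, evidence-gated network assembly, co-expression
# baseline, external support annotation, summaries and sign-bias testing.

mk_edges <- function(n_act, n_inh, lnc = "L1") {
  n <- n_act + n_inh
  data.frame(lncrna_id = rep(lnc, n),
             target_id = paste0(lnc, "_g", seq_len(n), recycle0 = TRUE),
             sign = c(rep(1, n_act), rep(-1, n_inh)))
}

test_that("strong-pair gates use the published threshold semantics", {
  ga <- generate_annotation(small_config(seed = 3))
  ann <- ga$annotation
  lnc <- ann$gene_id[ann$class == "lncRNA"][1:2]
  tgt <- ann$gene_id[ann$class == "mRNA"][1:2]
  base <- as.numeric(gaussian_predictors(1, 60, seed = 1))
  noise <- gaussian_predictors(4, 60, seed = 2)
  expr <- rbind(base + 0.01 * noise[1, ], base + 0.01 * noise[2, ],
                base + 0.01 * noise[3, ], base + 0.01 * noise[4, ])
  rownames(expr) <- c(lnc, tgt)
  ft <- data.frame(target_id = rep(tgt, each = 1),
                   predictor_id = lnc,
                   coefficient = 1, coef_p = c(1e-12, 1e-9),  # 1e-9 fails <= 1e-10
                   overall_r2 = 0.5, mean_test_r2 = 0.5)
  ep <- stats::setNames(c(0, 0), tgt)
  out <- strong_pairs(ft, ep, expr, ann, ga$tads)
  expect_equal(nrow(out$pairs), 1)
  expect_equal(out$pairs$coef_p, 1e-12)
  # empty input passes through
  expect_equal(nrow(strong_pairs(ft[0, ], ep, expr, ann, ga$tads)$pairs), 0)
  # the empirical-p gate is strict (< 0.01): a target at exactly 0.01 fails
  ep2 <- stats::setNames(c(0.01, 0), tgt)
  out2 <- strong_pairs(ft, ep2, expr, ann, ga$tads)
  expect_false(tgt[1] %in% out2$pairs$target_id)
})

test_that("network assembly gates edges by evidence, R2 and coefficient p", {
  n <- 300
  lncs <- gaussian_predictors(4, n, seed = 10, prefix = "L")
  y_good <- as.numeric(scale(lncs["L1", ] + lncs["L2", ] + rnorm(n, sd = 0.6)))
  expr <- rbind(lncs, tgt = y_good)
  ev <- data.frame(target_id = "tgt", lncrna_id = c("L1", "L2", "L3"),
                   sig_p = c(1e-6, 1e-6, 1e-6),
                   overlapping = c(TRUE, FALSE, FALSE),
                   cerna = c(FALSE, TRUE, FALSE))
  net <- assemble_network(ev, expr)
  # L3 has no evidence flag; L1, L2 are real regulators
  expect_setequal(net$edges$lncrna_id, c("L1", "L2"))
  expect_true(all(net$edges$coef_p <= 0.01))
  expect_true(all(net$edges$sign == 1))
  # flipping the target flips every incident sign
  expr2 <- expr; expr2["tgt", ] <- -expr2["tgt", ]
  net2 <- assemble_network(ev, expr2)
  expect_equal(net2$edges$sign, -net$edges$sign)
  # a candidate with evidence but a weak refit coefficient yields no edge
  ev3 <- data.frame(target_id = "tgt", lncrna_id = "L4", sig_p = 1e-6, cerna = TRUE)
  net3 <- assemble_network(ev3, expr)
  expect_equal(nrow(net3$edges), 0)
  # empty evidence: empty network
  expect_equal(nrow(assemble_network(ev[0, ], expr)$edges), 0)
  # containment: network pairs are a subset of the evidenced significant pairs
  expect_true(all(paste(net$edges$lncrna_id, net$edges$target_id) %in%
                    paste(ev$lncrna_id, ev$target_id)))
})

test_that("co-expression baseline returns the top-k pairs deterministically", {
  n <- 80
  base <- with_seed(20, rnorm(n))
  expr <- rbind(L1 = base + rnorm(n, sd = 0.1),
                L2 = with_seed(21, rnorm(n)),
                g1 = base + rnorm(n, sd = 0.1),
                g2 = with_seed(22, rnorm(n)))
  top1 <- coexpression_baseline(expr, c("L1", "L2"), c("g1", "g2"), 1)
  expect_equal(top1$lncrna_id, "L1")
  expect_equal(top1$target_id, "g1")
  expect_error(coexpression_baseline(expr, c("L1", "L2"), c("g1", "g2"), 10), "exceeds")
  # exact |PCC| ties resolve by lexicographic ids
  e2 <- rbind(La = c(1, 2, 3, 4), Lb = c(1, 2, 3, 4), gx = c(1, 2, 3, 4.5))
  t2 <- coexpression_baseline(e2, c("Lb", "La"), "gx", 1)
  expect_equal(t2$lncrna_id, "La")
})

test_that("external support respects the 1 Mbp window boundary", {
  ann <- data.frame(gene_id = c("L1", "G1"), gene_name = c("L1", "G1"),
                    class = c("lncRNA", "mRNA"), chrom = "chr1",
                    start = c(5e6, 10e6), end = c(5.01e6, 10.02e6), strand = "+")
  net <- structure(list(edges = data.frame(lncrna_id = "L1", target_id = "G1",
                                           coef = 1, coef_p = 1e-3, sign = 1)),
                   class = "lnc_network")
  inside <- data.frame(lncrna_id = "L1", chrom = "chr1", start = 10.005e6, end = 10.006e6)
  expect_true(annotate_external_support(net, inside, ann)$edges$external_support)
  at_window <- data.frame(lncrna_id = "L1", chrom = "chr1",
                          start = 11.02e6, end = 11.021e6)  # exactly 1 Mbp past the body
  expect_true(annotate_external_support(net, at_window, ann)$edges$external_support)
  beyond <- data.frame(lncrna_id = "L1", chrom = "chr1",
                       start = 11.020001e6, end = 11.021e6)  # 1 Mbp + 1 bp
  expect_false(annotate_external_support(net, beyond, ann)$edges$external_support)
})

test_that("network summaries reproduce printed degree arithmetic", {
  # published degree structure: 1157 edges over 508 lncRNAs and 232 targets
  e <- data.frame(
    lncrna_id = paste0("L", rep_len(1:508, 1157)),
    target_id = paste0("g", rep_len(1:232, 1157)),
    sign = rep_len(c(rep(1, 782), rep(-1, 355)), 1157))
  s <- network_summary(e)
  expect_equal(s$mean_out_degree_1dp, 2.3)
  expect_equal(s$mean_in_degree_1dp, 5.0)
  expect_equal(s$n_edges, 1157)
  s1 <- network_summary(mk_edges(1, 0))
  expect_equal(s1$mean_out_degree, 1)
  expect_equal(s1$mean_in_degree, 1)
  expect_error(network_summary(mk_edges(0, 0)), "empty")
})

test_that("sign-bias test matches an exact binomial oracle", {
  # 18 activating of 19 edges against a global fraction of 782/1137
  edges <- rbind(mk_edges(18, 1, "SN1"),
                 mk_edges(782 - 18, 355 - 1, "other"))
  out <- sign_bias_test(edges, "SN1")
  # 3-line oracle: upper binomial tail at the global activating fraction
  p0 <- mean(edges$sign > 0)
  oracle <- sum(dbinom(18:19, 19, p0))
  expect_equal(out$p_value, oracle, tolerance = 1e-12)
  expect_lt(out$p_value, 0.01)
  expect_equal(out$direction, "activating")
  # a lncRNA matching the global ratio is unremarkable either way
  bal <- rbind(mk_edges(7, 3, "L7"), mk_edges(70, 30, "bg"))
  expect_gt(sign_bias_test(bal, "L7")$p_value, 0.5)
  # degenerate global ratio is not evaluable
  expect_false(sign_bias_test(mk_edges(10, 0, "La"), "La")$evaluable)
  # below the minimum out-degree the test is not evaluable
  expect_false(sign_bias_test(rbind(mk_edges(3, 1, "Lb"), mk_edges(20, 10, "bg")),
                              "Lb")$evaluable)
})
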