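toy_table <- function(inner, outer, agents = rep(c("Gd-DTPA", "Gd-BOPTA"),
                                                 each = length(inner) / 2)) {
  n <- length(inner)
  validate <- function(v) data.frame(
    node = rep(seq_len(n), each = 2), agent = rep(agents, each = 2),
    cluster = rep(c("inner", "outer"), n),
    auc = v, wash_in = v, wash_out = -v, volume_pct = rep(c(40, 60), n))
  validate(as.vector(rbind(inner, outer)))
}

test_that("identical clusters give a null cluster effect", {
  tab <- toy_table(inner = c(5, 7, 6, 8, 5, 9), outer = c(5, 7, 6, 8, 5, 9))
  a <- two_way_anova(tab, "auc")
  expect_equal(a$effects$F[a$effects$term == "cluster"], 0)
  expect_equal(a$effects$p[a$effects$term == "cluster"], 1)
  expect_equal(a$contrasts$estimate, c(0, 0))
})

test_that("F statistics match a hand-computed sums-of-squares oracle", {
  inner <- c(10, 12, 11, 20, 22, 21)
  outer <- c(7, 8, 6, 15, 17, 14)
  tab <- toy_table(inner, outer)
  a <- two_way_anova(tab, "auc")

  # brute-force decomposition for the balanced split-plot design:
  # between-node stratum: agent vs node-within-agent error;
  # within-node stratum: cluster, agent:cluster vs cluster-by-node residual
  v <- cbind(inner, outer)
  agent <- rep(c("D", "B"), each = 3)
  node_means <- rowMeans(v)
  grand <- mean(v)
  ss_agent <- sum(2 * 3 * (tapply(node_means, agent, mean) - grand)^2)
  ss_node <- 2 * sum((node_means - tapply(node_means, agent, mean)[
    match(agent, names(tapply(node_means, agent, mean)))])^2)
  cl_means <- colMeans(v)
  ss_cluster <- sum(6 * (cl_means - grand)^2)
  cell <- rbind(tapply(v[, 1], agent, mean), tapply(v[, 2], agent, mean))
  ss_cells <- 3 * sum((t(cell) - grand)^2)
  ss_int <- ss_cells - ss_agent - ss_cluster
  ss_tot <- sum((v - grand)^2)
  ss_resid <- ss_tot - ss_agent - ss_node - ss_cluster - ss_int

  F_agent <- (ss_agent / 1) / (ss_node / 4)
  F_cluster <- (ss_cluster / 1) / (ss_resid / 4)
  F_int <- (ss_int / 1) / (ss_resid / 4)
  expect_equal(a$effects$F[a$effects$term == "agent"], F_agent,
               tolerance = 1e-10)
  expect_equal(a$effects$F[a$effects$term == "cluster"], F_cluster,
               tolerance = 1e-10)
  expect_equal(a$effects$F[a$effects$term == "agent:cluster"], F_int,
               tolerance = 1e-10)
  expect_equal(a$mse_within, ss_resid / 4, tolerance = 1e-10)
})

test_that("within-agent contrasts agree with an emmeans oracle", {
  library(emmeans)
  tab <- load_param_table()
  a <- two_way_anova(tab, "wash_out")
  d <- data.frame(node = factor(tab$node), agent = factor(tab$agent),
                  cluster = factor(tab$cluster), value = tab$wash_out)
  fit <- do.call(stats::aov,
                 list(value ~ agent * cluster + Error(node), data = d))
  em <- summary(emmeans::contrast(
    emmeans::emmeans(fit, ~ cluster | agent, data = d),
    method = list("inner - outer" = c(1, -1))))
  em <- em[order(as.character(em$agent)), ]
  ours <- a$contrasts[order(a$contrasts$agent), ]
  expect_equal(ours$estimate, em$estimate, tolerance = 1e-8)
  expect_equal(ours$se, em$SE, tolerance = 1e-8)
  expect_equal(ours$p, em$p.value, tolerance = 1e-6)
})

test_that("duplicated groups null the agent effect; shifts dominate it", {
  dt <- load_param_table()
  dt <- dt[dt$agent == "Gd-DTPA", ]
  dup <- dt
  dup$agent <- "Gd-BOPTA"
  dup$node <- dt$node + 100
  tab <- validate_tab <- rbind(dt, dup)
  a <- two_way_anova(tab, "auc")
  expect_equal(a$effects$F[a$effects$term == "agent"], 0, tolerance = 1e-12)
  expect_equal(a$effects$p[a$effects$term == "agent"], 1, tolerance = 1e-12)

  shifted <- tab
  shifted$auc[shifted$agent == "Gd-BOPTA"] <-
    shifted$auc[shifted$agent == "Gd-BOPTA"] + 1e4
  a2 <- two_way_anova(shifted, "auc")
  expect_lt(a2$effects$p[a2$effects$term == "agent"], 1e-6)
})

test_that("label swap flips the cluster effect sign but not its p value", {
  tab <- load_param_table()
  swapped <- tab
  swapped$cluster <- ifelse(tab$cluster == "inner", "outer", "inner")
  for (pm in c("auc", "wash_out")) {
    a <- two_way_anova(tab, pm)
    b <- two_way_anova(swapped, pm)
    expect_equal(b$contrasts$estimate, -a$contrasts$estimate,
                 tolerance = 1e-10)
    expect_equal(b$contrasts$p, a$contrasts$p, tolerance = 1e-10)
    expect_equal(b$effects$p[b$effects$term == "cluster"],
                 a$effects$p[a$effects$term == "cluster"], tolerance = 1e-10)
  }
})

test_that("Bonferroni adjustment doubles and caps the raw p", {
  expect_equal(bonferroni(0.01, 2), 0.02)
  expect_equal(bonferroni(0.7, 2), 1)
  expect_equal(bonferroni(c(0.3, 0.6), 2), c(0.6, 1))
  a <- two_way_anova(load_param_table(), "auc")
  expect_equal(a$contrasts$p_adj, pmin(1, 2 * a$contrasts$p))
  expect_true(all(a$contrasts$p_adj >= a$contrasts$p))
})

test_that("single-agent tables omit agent terms but keep the contrast", {
  tab <- load_param_table()
  solo <- tab[tab$agent == "Gd-BOPTA", ]
  a <- two_way_anova(solo, "auc")
  expect_true(is.na(a$effects$F[a$effects$term == "agent"]))
  expect_equal(nrow(a$contrasts), 1L)
  expect_equal(a$contrasts$direction, "inner > outer")
  expect_error(agent_effect(solo), "both agents")
})
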