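# Mixed two-way ANOVA on the node parameter table: cluster (inner/outer) is
# a within-node factor, contrast agent a between-node factor, node the
# blocking unit. This is the only design consistent with paired inner/outer
# values per node. Within-agent inner-vs-outer contrasts use the pooled
# within-node error mean square and are Bonferroni-adjusted by a factor of 2
# (one contrast per agent, per parameter).

param_long <- function(tab, parameter) {
  parameter <- match.arg(parameter, c("auc", "wash_in", "wash_out",
                                      "volume_pct"))
  data.frame(node = factor(tab$node),
             agent = factor(tab$agent),
             cluster = factor(tab$cluster, levels = c("inner", "outer")),
             value = tab[[parameter]])
}

#' Mixed two-way ANOVA comparing clusters and contrast agents
#'
#' Fits \code{value ~ agent * cluster + Error(node)} on one parameter of a
#' node table: the agent main effect is tested in the between-node stratum,
#' the cluster main effect and agent:cluster interaction in the within-node
#' stratum. Within-agent inner-minus-outer contrasts use the within-stratum
#' residual mean square, with two-sided p values Bonferroni-adjusted by
#' factor 2.
#'
#' With a single agent in the table, agent terms are omitted and the
#' within-agent contrast is still computed.
#'
#' @param tab A [load_param_table()]-shaped table.
#' @param parameter One of \code{"auc"}, \code{"wash_in"}, \code{"wash_out"},
#'   \code{"volume_pct"}.
#' @return Object of class \code{nde_anova}: \code{effects} (F and p for
#'   cluster, agent, interaction), \code{contrasts} (per-agent estimate, SE,
#'   df, t, raw and adjusted p, direction), \code{mse_within}, \code{df_within}.
#' @export
two_way_anova <- function(tab, parameter) {
  d <- param_long(tab, parameter)
  agents <- levels(droplevels(d$agent))
  single_agent <- length(agents) < 2L
  for (a in agents)
    if (length(unique(d$node[d$agent == a])) < 2L)
      stop("need at least 2 nodes per agent", call. = FALSE)

  if (single_agent) {
    fit <- stats::aov(value ~ cluster + Error(node), data = d)
  } else {
    fit <- stats::aov(value ~ agent * cluster + Error(node), data = d)
  }
  sm <- summary(fit)
  within <- sm[["Error: Within"]][[1]]
  between <- sm[["Error: node"]][[1]]

  # sums of squares below this are numerical dust from an exactly null
  # effect; report F = 0, p = 1 rather than a 0/0 artifact
  ss_tol <- 1e-12 * sum(d$value^2) + .Machine$double.xmin
  g <- function(stratum, term, col) {
    i <- match(term, trimws(rownames(stratum)))
    if (is.na(i)) return(NA_real_)
    if (stratum[i, "Sum Sq"] < ss_tol)
      return(if (col == "F value") 0 else 1)
    stratum[i, col]
  }
  effects <- data.frame(
    term = c("cluster", "agent", "agent:cluster"),
    F = c(g(within, "cluster", "F value"),
          if (single_agent) NA_real_ else g(between, "agent", "F value"),
          if (single_agent) NA_real_ else g(within, "agent:cluster", "F value")),
    p = c(g(within, "cluster", "Pr(>F)"),
          if (single_agent) NA_real_ else g(between, "agent", "Pr(>F)"),
          if (single_agent) NA_real_ else g(within, "agent:cluster", "Pr(>F)"))
  )
  ri <- match("Residuals", trimws(rownames(within)))
  mse <- within[ri, "Mean Sq"]
  dfe <- within[ri, "Df"]
  if (mse < ss_tol) mse <- 0

  # per-agent inner - outer contrast on the pooled within-node error:
  # the mean of n_a per-node differences has variance 2*sigma^2/n_a
  contrasts <- do.call(rbind, lapply(agents, function(a) {
    da <- d[d$agent == a, ]
    wide <- merge(da[da$cluster == "inner", c("node", "value")],
                  da[da$cluster == "outer", c("node", "value")],
                  by = "node", suffixes = c("_inner", "_outer"))
    est <- mean(wide$value_inner - wide$value_outer)
    n_a <- nrow(wide)
    se <- sqrt(2 * mse / n_a)
    if (se == 0) {
      tval <- if (est == 0) 0 else sign(est) * Inf
      p <- if (est == 0) 1 else 0
    } else {
      tval <- est / se
      p <- 2 * stats::pt(-abs(tval), dfe)
    }
    data.frame(agent = a, estimate = est, se = se, df = dfe, t = tval,
               p = p, p_adj = bonferroni(p, 2L),
               direction = ifelse(est > 0, "inner > outer",
                                  ifelse(est < 0, "inner < outer", "equal")),
               stringsAsFactors = FALSE)
  }))

  structure(list(parameter = parameter, effects = effects,
                 contrasts = contrasts, mse_within = mse, df_within = dfe,
                 single_agent = single_agent),
            class = "nde_anova")
}

#' Bonferroni adjustment
#'
#' @param p Raw p value(s).
#' @param m Family size.
#' @return \code{pmin(1, m * p)}.
#' @export
bonferroni <- function(p, m) pmin(1, m * p)

#' Agent main effect across all parameters
#'
#' @param tab A node parameter table with both agents.
#' @return data.frame with one row per parameter: agent F and p.
#' @export
agent_effect <- function(tab) {
  params <- c("auc", "wash_in", "wash_out", "volume_pct")
  if (length(unique(tab$agent)) < 2L)
    stop("agent effect needs both agents in the table", call. = FALSE)
  do.call(rbind, lapply(params, function(pm) {
    a <- two_way_anova(tab, pm)
    data.frame(parameter = pm,
               F = a$effects$F[a$effects$term == "agent"],
               p = a$effects$p[a$effects$term == "agent"])
  }))
}

#' Full significance report over all four parameters
#'
#' Runs [two_way_anova()] for AUC, wash-in, wash-out and volume and collects
#' the per-agent Bonferroni-adjusted cluster contrasts with significance
#' stars (** p < 0.01, * p < 0.05, two-sided).
#'
#' @param tab A node parameter table.
#' @return data.frame with one row per (parameter, agent).
#' @export
significance_report <- function(tab) {
  params <- c("auc", "wash_in", "wash_out", "volume_pct")
  out <- do.call(rbind, lapply(params, function(pm) {
    a <- two_way_anova(tab, pm)
    cbind(parameter = pm, a$contrasts)
  }))
  out$signif <- ifelse(out$p_adj < 0.01, "**",
                       ifelse(out$p_adj < 0.05, "*", ""))
  out
}

#' @export
print.nde_anova <- function(x, ...) {
  cat(sprintf("<nde_anova> parameter: %s\n", x$parameter))
  cat("  effects:\n")
  print(x$effects, row.names = FALSE)
  cat("  within-agent inner - outer contrasts (Bonferroni x2):\n")
  print(x$contrasts[, c("agent", "estimate", "t", "df", "p", "p_adj",
                        "direction")], row.names = FALSE)
  invisible(x)
}
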