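#!/usr/bin/env Rscript
# Diagnostic figures: an annotated example retract curve, the per-condition
# work distributions for each sweep, and the fitted model curves over the
# condition means. PDFs land in results/figs/.

library(ccfs)
suppressPackageStartupMessages(library(ggplot2))

dir.create("results/figs", recursive = TRUE, showWarnings = FALSE)

## annotated example curve ----------------------------------------------------
cfg <- simulation_config()
traj <- simulate_contact_phase(cfg)
n <- draw_bond_count(traj, cfg$k_on, seed = 2026)
sim <- synthesize_retract_curve(cfg, n, seed = 2027)
res <- analyze_curve(sim$curve)
cdf <- data.frame(z = sim$curve$z - res$origin_z, force = sim$curve$force)
p1 <- ggplot(cdf, aes(z, force)) +
  geom_hline(yintercept = res$baseline_level, linetype = 3) +
  geom_line(linewidth = 0.3, colour = "darkgreen") +
  geom_vline(xintercept = res$events$z_position, alpha = 0.3) +
  annotate("point", x = res$z_det, y = res$f_det, colour = "red", size = 2) +
  coord_cartesian(xlim = c(-1, res$z_det * 1.2)) +
  labs(x = "Z (um, from baseline crossing)", y = "force (nN)",
       title = sprintf("simulated retract curve: W = %.1f fJ, %d events",
                       res$work, nrow(res$events)))
ggsave("results/figs/example_curve.pdf", p1, width = 7, height = 4)

## distributions and fits per sweep -------------------------------------------
model_curve <- function(fit, x) {
  ms <- model_spec(fit$model_id)
  data.frame(x = x, y = ms$fun(x, fit$A, fit$B))
}
sweep_plot <- function(model, xlab, log_x = FALSE) {
  res <- read.csv(sprintf("results/tables/results_%s.csv", model),
                  stringsAsFactors = FALSE)
  ms <- model_spec(model)
  res <- res[!is.na(res$work_fJ), ]
  summ <- aggregate_by_condition(res, ms$variable)
  fit <- fit_model(summ, model)
  grid <- seq(min(summ$value) * 0.9, max(summ$value) * 1.05,
              length.out = 200)
  grid <- grid[grid > 0]
  p <- ggplot(res, aes(x = .data[[ms$variable]], y = work_fJ,
                       group = .data[[ms$variable]])) +
    geom_boxplot(outlier.size = 0.5, width = diff(range(summ$value)) / 25) +
    geom_point(data = summ, aes(x = value, y = mean_W), inherit.aes = FALSE,
               colour = "red", size = 2) +
    geom_line(data = model_curve(fit, grid), aes(x, y), inherit.aes = FALSE,
              colour = "red") +
    labs(x = xlab, y = "detachment work W (fJ)",
         title = sprintf("%s sweep: A = %.3g, B = %.3g", model, fit$A, fit$B))
  if (log_x) p <- p + scale_x_log10()
  p
}
ggsave("results/figs/sweep_delay.pdf", sweep_plot("delay", "dwell time (s)"),
       width = 6, height = 4)
ggsave("results/figs/sweep_setpoint.pdf",
       sweep_plot("setpoint", "setpoint force (nN)"), width = 6, height = 4)
ggsave("results/figs/sweep_approach.pdf",
       sweep_plot("approach", "approach speed (um/s)"), width = 6, height = 4)
ggsave("results/figs/sweep_retract.pdf",
       sweep_plot("retract", "retract speed (um/s)"), width = 6, height = 4)

## delay-mode comparison -------------------------------------------------------
res_mode <- read.csv("results/tables/results_mode.csv",
                     stringsAsFactors = FALSE)
res_mode <- res_mode[!is.na(res_mode$work_fJ), ]
p5 <- ggplot(res_mode, aes(delay_mode, work_fJ)) +
  geom_boxplot(width = 0.4) +
  geom_jitter(width = 0.08, alpha = 0.4, size = 0.8) +
  labs(x = NULL, y = "detachment work W (fJ)",
       title = "dwell feedback mode comparison")
ggsave("results/figs/delay_mode.pdf", p5, width = 5, height = 4)

cat("figures written to results/figs/\n")
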