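#' @export
print.bite_base_sim <- function(x, ...) {
  fin <- x$summary[nrow(x$summary), ]
  cat("Base-model IS formation simulation\n")
  cat(sprintf("  %d replicates, %.0f min, %.3g total cells/mL, E:T %.3g, %g ng/mL\n",
              x$config$replicates, fin$time_min,
              x$config$total_density_per_ml, x$config$et_ratio,
              x$config$bite_ngml))
  cat(sprintf("  effector engagement at end: %.2f%% (SE %.2f)\n",
              100 * fin$effector_engaged, 100 * fin$effector_engaged_se))
  cat(sprintf("  target engagement at end:   %.2f%% (SE %.2f)\n",
              100 * fin$target_engaged, 100 * fin$target_engaged_se))
  cat(sprintf("  synapse entities pooled over replicates: %d\n",
              nrow(x$entities)))
  invisible(x)
}

#' @export
summary.bite_base_sim <- function(object, ...) {
  sv <- summarize_variants(object$entities)
  fin <- object$summary[nrow(object$summary), ]
  out <- list(final_effector_engaged_pct = 100 * fin$effector_engaged,
              final_target_engaged_pct = 100 * fin$target_engaged,
              variants = sv, timeseries = object$summary)
  class(out) <- "summary.bite_base_sim"
  out
}

#' @export
print.summary.bite_base_sim <- function(x, ...) {
  cat(sprintf("Final engagement: effectors %.2f%%, targets %.2f%%\n",
              x$final_effector_engaged_pct, x$final_target_engaged_pct))
  sv <- x$variants
  if (sv$n_entities > 0) {
    cat(sprintf("Synapses: %d, variant fraction %.1f%%\n", sv$n_entities,
                100 * sv$variant_fraction))
    cat("Variant composition (%):\n")
    print(round(100 * sv$composition, 1))
    cat(sprintf("Median E:T in synapses %.2f; in variants %.2f\n",
                sv$median_et_all, sv$median_et_variants))
  } else cat("No synapses formed\n")
  invisible(x)
}

#' @export
plot.bite_base_sim <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$time_min, 100 * s$effector_engaged, type = "l",
                 xlab = "time (min)", ylab = "engaged (%)",
                 ylim = c(0, max(100 * s$effector_engaged,
                                 100 * s$target_engaged) * 1.1), ...)
  graphics::lines(s$time_min, 100 * s$target_engaged, lty = 2)
  graphics::legend("topleft", legend = c("effectors", "targets"),
                   lty = c(1, 2), bty = "n")
  invisible(x)
}

#' @export
print.bite_invitro_sim <- function(x, ...) {
  cat("In vitro serial-engagement simulation\n")
  cat(sprintf("  %d replicates, %g h, %.3g total cells/mL, %g ng/mL\n",
              x$config$replicates, x$config$duration_h,
              x$config$total_density_per_ml, x$config$bite_ngml))
  cat(sprintf("  final target lysis: %.1f%% (SE %.1f)\n",
              100 * x$summary["mean"], 100 * x$summary["se"]))
  ev <- x$evolution
  last <- ev[ev$time_h == max(ev$time_h), ]
  cat(sprintf("  survivor mean CD19 at %g h: %.3g (initial %.3g)\n",
              max(ev$time_h), mean(last$mean_cd19),
              mean(ev$mean_cd19[ev$time_h == 0])))
  invisible(x)
}

#' @export
plot.bite_invitro_sim <- function(x, ...) {
  agg <- stats::aggregate(lysis_fraction ~ time_h, data = x$lysis, FUN = mean)
  graphics::plot(agg$time_h, 100 * agg$lysis_fraction, type = "l",
                 xlab = "time (h)", ylab = "target lysis (%)", ...)
  invisible(x)
}

#' @export
print.bite_invivo_sim <- function(x, ...) {
  cat("In vivo organ-compartment simulation\n")
  cat(sprintf("  regimen %s/scheme %d, %g weeks, growth %.3g/day, T:B %.3g\n",
              x$regimen$level, x$regimen$scheme, x$config$duration_weeks,
              x$profile$growth_per_day, x$profile$t_b_ratio))
  cat(sprintf("  systemic B cells: baseline %.3g, final %.3g (%.2f log10 kill)\n",
              x$totals["baseline"], x$totals["final"],
              x$totals["kill_log10"]))
  cat("  per-organ lysis shares (%):\n")
  ol <- x$organ_lysis
  print(stats::setNames(round(ol$share_of_lysed_pct, 1), ol$organ))
  invisible(x)
}

#' @export
plot.bite_invivo_sim <- function(x, ...) {
  b <- x$blood_b
  graphics::plot(b$time_h / 24, pmax(b$b_per_ul, 1e-3), type = "l",
                 log = "y", xlab = "time (days)",
                 ylab = "blood B cells (/uL)", ...)
  invisible(x)
}

#' @export
print.bite_lysis_grid <- function(x, ...) {
  cat("72-h target lysis (%) over effector x target density grid\n")
  print(round(x$lysis_pct, 1))
  if (!is.null(x$organs)) {
    cat("organ overlay densities:\n")
    print(x$organs)
  }
  invisible(x)
}
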