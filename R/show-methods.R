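## Compact show() methods for the S4 containers.

setMethod("show", "ExchangeSystem", function(object) {
  cat(sprintf(paste0("ExchangeSystem: pA=%.3g pB=%.3g | nuA=%.6g nuB=%.6g Hz",
                     " | R2=%.3g/%.3g 1/s | kEx=%.4g 1/s\n"),
              object@pA, object@pB, object@nuA, object@nuB,
              object@r2A, object@r2B, object@kEx))
})

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum: %d points, %.6g..%.6g Hz, max intensity %.4g\n",
              length(object@freq), min(object@freq), max(object@freq),
              max(object@intensity)))
})

setMethod("show", "ArrheniusTruth", function(object) {
  cat(sprintf("ArrheniusTruth: Ea=%.4g kcal/mol, lnA=%.4g, T={%s} K\n",
              object@ea, object@lnA,
              paste(object@temperatures, collapse = ", ")))
})

setMethod("show", "EXSYDataset", function(object) {
  temps <- exsyTemperatures(object)
  cat(sprintf("EXSYDataset: %d curve(s) at %s K, %d points%s\n",
              length(temps), paste(temps, collapse = "/"),
              nrow(object@data),
              if (length(object@provenance)) " [with provenance]" else ""))
})

setMethod("show", "RateFit", function(object) {
  cat(sprintf(paste0("RateFit (%s): k=%.5g 1/s, t1/2=%.4g s, ",
                     "rss=%.3g%s%s\n"),
              object@modelTag, object@k, object@tHalf, object@residualSS,
              if (!is.na(object@temperature))
                sprintf(", T=%g K", object@temperature) else "",
              if (object@noExchange) " [no exchange]" else ""))
})

setMethod("show", "ArrheniusFit", function(object) {
  cat(sprintf("ArrheniusFit: Ea=%.4g kcal/mol, lnA=%.4g, R^2=%.5f (%d T)%s\n",
              object@ea, object@lnA, object@rSquared, nrow(object@rates),
              if (object@narrowSpan) " [narrow span]" else ""))
})

setMethod("show", "TorsionPotential", function(object) {
  lab <- if (nzchar(object@preset)) object@preset else "custom"
  cat(sprintf("TorsionPotential (%s): %d cosine term(s)\n",
              lab, nrow(object@terms)))
  print(object@terms, row.names = FALSE)
})

setMethod("show", "TorsionTrajectory", function(object) {
  acc <- if (nrow(object@exchangeLog))
    mean(object@exchangeLog$accepted) else NA
  cat(sprintf(paste0("TorsionTrajectory: %d sweeps x %d replica(s), ",
                     "%g..%g K, seed %g%s\n"),
              nrow(object@angles), ncol(object@angles),
              min(object@ladder), max(object@ladder), object@seed,
              if (!is.na(acc)) sprintf(", swap acceptance %.2f", acc) else ""))
})

setMethod("show", "TorsionProfileReport", function(object) {
  cat(sprintf(paste0("TorsionProfileReport: %d well(s) at {%s} deg, ",
                     "barrier(s) {%s} kcal/mol\n  occupancies {%s}, ",
                     "%d transition(s), ergodic: %s\n"),
              length(object@minima),
              paste(sprintf("%.1f", object@minima), collapse = ", "),
              paste(sprintf("%.2f", object@barriers), collapse = ", "),
              paste(sprintf("%.3f", object@occupancies), collapse = ", "),
              object@transitions, object@ergodic))
})

setMethod("show", "ConformerEnsemble", function(object) {
  cat(sprintf(paste0("ConformerEnsemble: %d conformer(s), %d torsion(s), ",
                     "%d predicted observable(s)%s\n"),
              nConformers(object), ncol(object@torsions),
              ncol(object@predicted),
              if (length(object@coords)) ", with coordinates" else ""))
})

setMethod("show", "ObservedData", function(object) {
  tab <- table(object@observables$kind)
  cat(sprintf("ObservedData: %d observable(s) (%s)\n",
              nrow(object@observables),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "PopulationFit", function(object) {
  w <- sort(object@weights, decreasing = TRUE)
  w <- w[w > 0]
  cat(sprintf("PopulationFit: ssd=%.4g, %d populated conformer(s)%s\n",
              object@ssd, length(w),
              if (length(object@pruned))
                sprintf(", %d pruned", length(object@pruned)) else ""))
  print(round(utils::head(w, 8), 4))
})

setMethod("show", "ShiftList", function(object) {
  cat(sprintf("ShiftList%s: %g MHz, %s, %d entries (%g H total)%s\n",
              if (nzchar(object@compound))
                paste0(" [", object@compound, "]") else "",
              object@frequencyMHz, object@solvent, nrow(object@entries),
              totalProtons(object),
              if (length(object@problems))
                sprintf(", %d problem(s)", length(object@problems)) else ""))
})
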