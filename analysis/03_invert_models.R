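#!/usr/bin/env Rscript
# Stage 3: invert the electrical and mechanical models per cell.
#
# The electrical chain turns (A_1kHz, A_100kHz, phase_100kHz, L_elongation)
# into specific membrane capacitance and cytoplasm conductivity; the
# mechanical inversion turns (L_instantaneous, L_transitional) plus the
# per-cell aspiration pressure into the instantaneous Young's modulus and
# the friction coefficient. Pressure is not part of the deposited raw
# layout, so it is taken from the ground-truth table of stage 1; with real
# deposited data this column is unavailable and E would stay missing.

suppressPackageStartupMessages(library(squeezecyto))

markers <- as.data.frame(data.table::fread("results/markers_H460.csv"))
truth <- as.data.frame(data.table::fread("results/truth_H460.csv"))
geom <- channel_geometry()
medium <- medium_model()

rows <- lapply(seq_len(nrow(markers)), function(i) {
  m <- markers[i, ]
  out <- data.frame(cell = m$cell, A_1kHz = m$A_1kHz, A_100kHz = m$A_100kHz,
                    L_instantaneous = m$L_instantaneous,
                    L_transitional = m$L_transitional,
                    L_elongation = m$L_elongation,
                    C_specific_membrane = NA_real_, sigma_cytoplasm = NA_real_,
                    E_instantaneous = NA_real_, f_c = NA_real_,
                    D_cell = NA_real_, status = m$status)
  if (m$status != "ok") return(out)
  out$D_cell <- diameter_from_elongation(m$L_elongation, geom)
  elec <- tryCatch(invert_electrical(m$A_1kHz, m$A_100kHz, m$phase_100kHz,
                                     geom, medium, m$L_elongation),
                   error = function(e) NULL)
  if (is.null(elec)) { out$status <- "electrical_no_convergence"; return(out) }
  out$C_specific_membrane <- elec$C_specific_membrane
  out$sigma_cytoplasm <- elec$sigma_cytoplasm
  p <- truth$P_aspiration[match(m$cell, truth$cell)]
  mech <- invert_entry(m$L_instantaneous, m$L_transitional, geom$d_channel, p)
  if (mech$status == "no_solution") { out$status <- "mech_no_solution"; return(out) }
  out$E_instantaneous <- mech$E_instantaneous
  out$f_c <- mech$f_c
  out
})
records <- do.call(rbind, rows)
write_marker_table(records, "results/records_H460.csv")

cat(sprintf("inverted %d/%d cells -> results/records_H460.csv\n",
            sum(records$status == "ok"), nrow(records)))
print(table(records$status))
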