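# Independently coded straight-line oracles for the closed-form budget
# equations. Deliberately written as scalar arithmetic (loops, algebraically
# rearranged constants), never calling the package's vectorized
# implementations.

oracle_coral_term <- function(m, px, d, g) m * px * d * g * 10

oracle_porites_g <- function(depth) {
  if (depth < 6) 1.337 - 0.021 * depth
  else 1.62 * exp(-0.032 * depth)
}

oracle_cca <- function(pca) 0.36 * pca

oracle_halimeda <- function(ph) 1.694 * ph

oracle_gross <- function(r, x, ca, h) r * x + r * ca + r * h

oracle_bite_volume <- function(L) exp(1.3172) * exp(0.0624 * L) * 0.001

oracle_scar <- function(L) 1 / (1 + exp(2.46142 - 0.08864 * L))

oracle_bite_rate <- function(L, brc, bitetime = 10)
  60 * abs(3.955 + brc - 0.045 * bitetime * L)

oracle_parrotfish_belt <- function(lengths, brcs, D) {
  tot <- 0
  for (i in seq_along(lengths)) {
    v <- oracle_bite_volume(lengths[i])
    s <- oracle_scar(lengths[i])
    b <- oracle_bite_rate(lengths[i], brcs[i])
    tot <- tot + v * s * b * D * 365 * 0.001 / (25 * 5)
  }
  tot
}

oracle_urchin_ind <- function(group, diam) {
  ab <- switch(group,
               diadematidae = c(0.000003, 3.2887),
               echinometra = c(0.0003, 1.9671),
               other_eroding = c(0.00003, 2.6414),
               non_eroding = return(0))
  ab[1] * diam^ab[2] * 0.365 * 0.57
}

oracle_urchin_quadrat <- function(groups, diams, area = 0.25) {
  tot <- 0
  for (i in seq_along(groups))
    tot <- tot + oracle_urchin_ind(groups[i], diams[i])
  tot / area
}

oracle_macro <- function(r, pmacro) r * 0.21 * pmacro
oracle_micro <- function(r, pmicro) r * 0.20 * pmicro

oracle_net <- function(gross, bio, sed = 0.53) gross + sed - bio

oracle_accretion <- function(Cp) Cp - 0.01949 * Cp^2

# tiny builders for hand-made transects -------------------------------------

make_intercepts <- function(transect_id, spec) {
  # spec: named integer vector category -> cm; names like "coral:Taxon"
  cats <- character(0); taxa <- character(0)
  for (nm in names(spec)) {
    parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
    cats <- c(cats, rep(parts[1], spec[[nm]]))
    taxa <- c(taxa, rep(if (length(parts) > 1) parts[2] else NA_character_,
                        spec[[nm]]))
  }
  tibble::tibble(transect_id = transect_id,
                 position_cm = seq_along(cats),
                 category = cats, taxon = taxa)
}

make_transect_row <- function(transect_id, contour_m, site = "S1",
                              depth = 6) {
  tibble::tibble(transect_id = transect_id, site_id = site, depth_m = depth,
                 planar_length_m = 2, contour_length_m = contour_m)
}
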