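#' Synthetic polypeptide model for structural-comparison tests
#'
#' Generates an alpha-helical C-alpha trace (2.3 A helix radius,
#' 1.5 A rise, 100 degrees per residue) bent along a gentle superhelix
#' so selections are never collinear, with approximate backbone N, C
#' and O atoms and side-chain tip atoms for charged residues (NZ for
#' Lys, OE1 for Glu).  Residue names cycle through a fixed mixed
#' sequence.  Purely synthetic: a geometry fixture, not a physical
#' protein model.
#'
#' @param n_res number of residues.
#' @param chain chain identifier.
#' @param start_res first residue number.
#' @return an [atomic_model()].
#' @export
synthetic_chain_model <- function(n_res = 120, chain = "A",
                                  start_res = 1L) {
  resnames <- rep(c("ALA", "LEU", "LYS", "GLU", "GLY", "VAL", "SER",
                    "ILE", "ARG", "ASP"), length.out = n_res)
  rows <- vector("list", n_res)
  for (i in seq_len(n_res)) {
    t <- (i - 1) * 100 * pi / 180
    z <- (i - 1) * 1.5
    # superhelical bend so the chain explores 3D
    bx <- 25 * cos(z / 60)
    by <- 25 * sin(z / 60)
    ca <- c(bx + 2.3 * cos(t), by + 2.3 * sin(t), z)
    nn <- ca + c(-0.8 * sin(t), 0.8 * cos(t), -1.0)
    cc <- ca + c(0.9 * sin(t), -0.9 * cos(t), 1.0)
    oo <- cc + c(0.6 * cos(t), 0.6 * sin(t), 0.4)
    at <- data.frame(
      chain = chain, resno = start_res + i - 1L, resid = resnames[i],
      elety = c("N", "CA", "C", "O"),
      elesy = c("N", "C", "C", "O"),
      x = c(nn[1], ca[1], cc[1], oo[1]),
      y = c(nn[2], ca[2], cc[2], oo[2]),
      z = c(nn[3], ca[3], cc[3], oo[3]),
      o = 1, b = 0, insert = "")
    if (resnames[i] %in% c("LYS", "GLU")) {
      tip <- ca + 3.5 * c(cos(t), sin(t), 0)
      at <- rbind(at, data.frame(
        chain = chain, resno = start_res + i - 1L, resid = resnames[i],
        elety = if (resnames[i] == "LYS") "NZ" else "OE1",
        elesy = if (resnames[i] == "LYS") "N" else "O",
        x = tip[1], y = tip[2], z = tip[3], o = 1, b = 0, insert = ""))
    }
    rows[[i]] <- at
  }
  atomic_model(do.call(rbind, rows))
}
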