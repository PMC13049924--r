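# Shared fixture builders. Everything is generated in code; no binary data.

pdbLine <- function(serial, name, resname, chain, resid, x, y, z,
                    occ = 1, elem = NULL, rec = "ATOM", altloc = " ") {
  if (is.null(elem)) elem <- substr(sub("^[0-9]+", "", name), 1, 1)
  nm <- if (nchar(name) < 4) paste0(" ", name) else name
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          rec, serial, nm, altloc, resname, chain, resid, x, y, z, occ, 0, elem)
}

# A hand-countable 3-residue peptide: GLY (4 atoms), SER (6), HIS (9) = 19.
writeTripeptidePdb <- function(path) {
  ln <- c(
    pdbLine(1, "N", "GLY", "A", 1, 0, 0, 0),
    pdbLine(2, "CA", "GLY", "A", 1, 1.2, 0.8, 0),
    pdbLine(3, "C", "GLY", "A", 1, 2.5, 0, 0),
    pdbLine(4, "O", "GLY", "A", 1, 2.5, 1.2, 0.8),
    pdbLine(5, "N", "SER", "A", 2, 4, 0, 0),
    pdbLine(6, "CA", "SER", "A", 2, 5.2, 0.8, 0),
    pdbLine(7, "CB", "SER", "A", 2, 5.2, 2.1, 0.5),
    pdbLine(8, "OG", "SER", "A", 2, 5.2, 3.2, -0.3),
    pdbLine(9, "C", "SER", "A", 2, 6.5, 0, 0),
    pdbLine(10, "O", "SER", "A", 2, 6.5, 1.2, 0.8),
    pdbLine(11, "N", "HIS", "A", 3, 8, 0, 0),
    pdbLine(12, "CA", "HIS", "A", 3, 9.2, 0.8, 0),
    pdbLine(13, "CB", "HIS", "A", 3, 9.2, 2.1, 0.5),
    pdbLine(14, "CG", "HIS", "A", 3, 9.2, 3.3, -0.2),
    pdbLine(15, "ND1", "HIS", "A", 3, 8.4, 4.2, 0.2),
    pdbLine(16, "CE1", "HIS", "A", 3, 8.8, 5.2, -0.6),
    pdbLine(17, "NE2", "HIS", "A", 3, 9.7, 4.9, -1.4),
    pdbLine(18, "C", "HIS", "A", 3, 10.5, 0, 0),
    pdbLine(19, "O", "HIS", "A", 3, 10.5, 1.2, 0.8),
    "END")
  writeLines(ln, path)
  path
}

# Simple ensemble directly from an array of frames over a toy topology.
toyEnsemble <- function(topology, frames, ...) {
  arr <- array(0, c(length(frames), nrow(essdyn::atoms(topology)), 3))
  for (f in seq_along(frames)) arr[f, , ] <- frames[[f]]
  essdyn:::newEnsemble(topology, arr, ...)
}

rotationZ <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
         byrow = TRUE)
}
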