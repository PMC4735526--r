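# Builders for synthetic structure fixtures: fixed-column PDB text and
# in-memory structure_model objects.

pdb_line <- function(serial, name, resid, chain, resno, x, y, z, element,
                     alt = "", type = "ATOM") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, nm, alt, substr(resid, 1, 3), chain, resno,
          x, y, z, 1, 0, element)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# structure_model straight from a coordinate matrix (synthetic, no file)
mk_model <- function(xyz, chain = "A", elety = "CA", element = "C",
                     resid = "GLY", resno = NULL, type = "ATOM") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(resno)) resno <- seq_len(n)
  atoms <- data.frame(type = rep_len(type, n), chain = rep_len(chain, n),
                      resno = resno, insert = "",
                      resid = rep_len(resid, n),
                      elety = rep_len(elety, n),
                      element = rep_len(element, n),
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      stringsAsFactors = FALSE)
  structure(list(atoms = atoms, accession = "synthetic"),
            class = "structure_model")
}

# combine models (e.g. two chains into a dimer)
bind_models <- function(...) {
  ms <- list(...)
  structure(list(atoms = do.call(rbind, lapply(ms, `[[`, "atoms")),
                 accession = "synthetic"),
            class = "structure_model")
}

rotate_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}

# deterministic blob of pseudo-atoms for SASA / superposition tests
random_blob <- function(n, seed, sd = 3) {
  set.seed(seed)
  matrix(rnorm(3 * n, sd = sd), n, 3)
}

# golden-spiral unit sphere points (re-derived here for cage fixtures)
.sphere_points_test <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}
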