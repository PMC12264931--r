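# Shared fixtures built in code: textbook geometries and small synthetic
# sets. All coordinates in Angstrom.

fix_h2 <- function(d = 0.74) {
  molecule(c("H", "H"), coords = rbind(c(0, 0, 0), c(d, 0, 0)), id = "h2")
}

fix_benzene <- function() {
  th <- (0:5) * pi / 3
  molecule(c(rep("C", 6), rep("H", 6)),
           coords = rbind(cbind(1.39 * cos(th), 1.39 * sin(th), 0),
                          cbind(2.48 * cos(th), 2.48 * sin(th), 0)),
           id = "benzene")
}

fix_ethane <- function() {
  molecule(c("C", "C", "H", "H", "H", "H", "H", "H"),
           coords = rbind(c(0, 0, 0), c(1.54, 0, 0),
                          c(-0.52, 0.87, 0.30), c(-0.52, -0.80, 0.45),
                          c(-0.50, -0.05, -1.02), c(2.06, 0.87, -0.30),
                          c(2.06, -0.80, -0.45), c(2.04, -0.05, 1.02)),
           id = "ethane")
}

fix_ethene <- function() {
  molecule(c("C", "C", "H", "H", "H", "H"),
           coords = rbind(c(0, 0, 0), c(1.33, 0, 0),
                          c(-0.54, 0.93, 0), c(-0.54, -0.93, 0),
                          c(1.87, 0.93, 0), c(1.87, -0.93, 0)),
           id = "ethene")
}

fix_ethyne <- function() {
  molecule(c("C", "C", "H", "H"),
           coords = rbind(c(0, 0, 0), c(1.20, 0, 0),
                          c(-1.06, 0, 0), c(2.26, 0, 0)),
           id = "ethyne")
}

fix_water <- function() {
  molecule(c("O", "H", "H"),
           coords = rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
           id = "water")
}

fix_methane <- function() {
  molecule(c("C", "H", "H", "H", "H"),
           coords = rbind(c(0, 0, 0), c(0.63, 0.63, 0.63),
                          c(-0.63, -0.63, 0.63), c(-0.63, 0.63, -0.63),
                          c(0.63, -0.63, -0.63)),
           id = "methane")
}

# a small perceived set built from SMILES (bond orders + aromatic flags)
fix_smiles_set <- function(smiles, label = "train") {
  tf <- tempfile(fileext = ".smi")
  on.exit(unlink(tf))
  writeLines(smiles, tf)
  read_molecules(tf, "smiles", label)
}

# random rotation matrix from a fixed seed
fix_rotation <- function(seed = 1) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}
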