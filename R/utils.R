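# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalise a zero-length vector")
  v / n
}

# angle at `center` between two points, degrees in [0, 180]
angle_deg <- function(a, center, b) {
  u <- a - center
  v <- b - center
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

rms <- function(x) sqrt(mean(x^2))

# residue key: chain:resno:ins:comp -- author numbering throughout
make_res_key <- function(chain, resno, ins, comp_id) {
  ins <- ifelse(is.na(ins) | ins == "", "", ins)
  paste(chain, resno, ins, comp_id, sep = ":")
}

# coordinate matrix (n x 3) for a set of atom rows
coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

# distances from a point to every row of an atom tibble (vectorised)
dist_to_point <- function(atoms, p) {
  sqrt((atoms$x - p[1])^2 + (atoms$y - p[2])^2 + (atoms$z - p[3])^2)
}

# random 3D rotation matrix (uniform over SO(3), via QR of a Gaussian matrix)
random_rotation <- function() {
  m <- matrix(rnorm(9), 3, 3)
  qr_ <- qr(m)
  q <- qr.Q(qr_)
  d <- diag(qr.R(qr_))
  q <- q %*% diag(sign(d))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

phosphate_oxygens <- c("OP1", "OP2", "OP3", "O5'", "O3'")
ribose_oxygens <- c("O2'", "O4'")

standard_ribonucleotides <- c("A", "C", "G", "U", "I", "N")
standard_amino_acids <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL"
)
metal_elements <- c("MG", "K", "NA", "ZN", "MN", "CA", "FE")
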