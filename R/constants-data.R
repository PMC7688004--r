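# Physicochemical reference data (AAindex and related published tables).
# Residue order throughout: A R N D C Q E G H I L K M F P S T W Y V
# Generated from published sources; do not edit numbers by hand.

AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Average (isotope-weighted) residue masses, Da; water 18.01524 Da.
RESIDUE_MASS <- c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388, Q = 128.1307, E = 129.1155, G = 57.0519, H = 137.1411, I = 113.1594, L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167, S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01524

# Per-residue physicochemical scales used by the autocorrelation,
# sequence-order and pseudo-composition descriptors.
AA_SCALES <- list(
  # Normalized average hydrophobicity (Cid et al. 1992)
  hydrophobicity = c(A = 0.02, R = -0.42, N = -0.77, D = -1.04, C = 0.77, Q = -1.10, E = -1.14, G = -0.80, H = 0.26, I = 1.81, L = 1.14, K = -0.41, M = 1.00, F = 1.35, P = -0.09, S = -0.97, T = -0.77, W = 1.71, Y = 1.11, V = 1.13),
  # Average flexibility index (Bhaskaran & Ponnuswamy 1988)
  flexibility = c(A = 0.357, R = 0.529, N = 0.463, D = 0.511, C = 0.346, Q = 0.493, E = 0.497, G = 0.544, H = 0.323, I = 0.462, L = 0.365, K = 0.466, M = 0.295, F = 0.314, P = 0.509, S = 0.507, T = 0.444, W = 0.305, Y = 0.420, V = 0.386),
  # Polarizability parameter (Charton & Charton 1982)
  polarizability = c(A = 0.046, R = 0.291, N = 0.134, D = 0.105, C = 0.128, Q = 0.180, E = 0.151, G = 0.000, H = 0.230, I = 0.186, L = 0.186, K = 0.219, M = 0.221, F = 0.290, P = 0.131, S = 0.062, T = 0.108, W = 0.409, Y = 0.298, V = 0.140),
  # Free energy of solution in water, kcal/mol (Charton & Charton 1982)
  free_energy = c(A = -0.368, R = -1.030, N = 0.000, D = 2.060, C = 4.530, Q = 0.731, E = 1.770, G = -0.525, H = 0.000, I = 0.791, L = 1.070, K = 0.000, M = 0.656, F = 1.060, P = -2.240, S = -0.524, T = 0.000, W = 1.600, Y = 4.910, V = 0.401),
  # Residue accessible surface area in tripeptide, A^2 (Chothia 1976)
  residue_asa = c(A = 115, R = 225, N = 160, D = 150, C = 135, Q = 180, E = 190, G = 75, H = 195, I = 175, L = 170, K = 200, M = 185, F = 210, P = 145, S = 115, T = 140, W = 255, Y = 230, V = 155),
  # Residue volume, A^3 (Bigelow 1967)
  residue_volume = c(A = 52.6, R = 109.1, N = 75.7, D = 68.4, C = 68.3, Q = 89.7, E = 84.7, G = 36.3, H = 91.9, I = 102.0, L = 102.0, K = 105.1, M = 97.7, F = 113.9, P = 73.6, S = 54.9, T = 71.2, W = 135.4, Y = 116.2, V = 85.1),
  # Steric parameter (Charton 1981)
  steric = c(A = 0.52, R = 0.68, N = 0.76, D = 0.76, C = 0.62, Q = 0.68, E = 0.68, G = 0.00, H = 0.70, I = 1.02, L = 0.98, K = 0.68, M = 0.78, F = 0.70, P = 0.36, S = 0.53, T = 0.50, W = 0.70, Y = 0.70, V = 0.76),
  # Relative mutability (Dayhoff et al. 1978)
  mutability = c(A = 100, R = 65, N = 134, D = 106, C = 20, Q = 93, E = 102, G = 49, H = 66, I = 96, L = 40, K = 56, M = 94, F = 41, P = 56, S = 120, T = 97, W = 18, Y = 41, V = 74),
  # Hydrophilicity (Hopp & Woods 1981)
  hydrophilicity = c(A = -0.5, R = 3.0, N = 0.2, D = 3.0, C = -1.0, Q = 0.2, E = 3.0, G = 0.0, H = -0.5, I = -1.8, L = -1.8, K = 3.0, M = -1.3, F = -2.5, P = 0.0, S = 0.3, T = -0.4, W = -3.4, Y = -2.3, V = -1.5),
  # Hydropathy index (Kyte & Doolittle 1982)
  hydropathy = c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2)
)

# Dipeptide instability weights (Guruprasad, Reddy & Pandit 1990).
# Rows: first residue of the dipeptide; columns: second residue.
DIWV <- matrix(c(
  1.0, 1.0, 1.0, -7.49, 44.94, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0,
  1.0, 58.28, 13.34, 1.0, 1.0, 20.26, 1.0, -7.49, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 20.26, 44.94, 1.0, 58.28, -6.54, 1.0,
  1.0, 1.0, 1.0, 1.0, -1.88, -6.54, 1.0, -14.03, 1.0, 44.94, 1.0, 24.68, 1.0, -14.03, -1.88, 1.0, -7.49, -9.37, 1.0, 1.0,
  1.0, -6.54, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, -6.54, 1.0, 20.26, -14.03, 1.0, 1.0, 1.0,
  1.0, 1.0, 1.0, 20.26, 1.0, -6.54, 1.0, 1.0, 33.6, 1.0, 20.26, 1.0, 33.6, 1.0, 20.26, 1.0, 33.6, 24.68, 1.0, -6.54,
  1.0, 1.0, 1.0, 20.26, -6.54, 20.26, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 20.26, 44.94, 1.0, 1.0, -6.54, -6.54,
  1.0, 1.0, 1.0, 20.26, 44.94, 20.26, 33.6, 1.0, -6.54, 20.26, 1.0, 1.0, 1.0, 1.0, 20.26, 20.26, 1.0, -14.03, 1.0, 1.0,
  -7.49, 1.0, -7.49, 1.0, 1.0, 1.0, -6.54, 13.34, 1.0, -7.49, 1.0, -7.49, 1.0, 1.0, 1.0, 1.0, -7.49, 13.34, -7.49, 1.0,
  1.0, 1.0, 24.68, 1.0, 1.0, 1.0, 1.0, -9.37, 1.0, 44.94, 1.0, 24.68, 1.0, -9.37, -1.88, 1.0, -6.54, -1.88, 44.94, 1.0,
  1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 44.94, 1.0, 13.34, 1.0, 20.26, -7.49, 1.0, 1.0, -1.88, 1.0, 1.0, 1.0, 1.0, -7.49,
  1.0, 20.26, 1.0, 1.0, 1.0, 33.6, 1.0, 1.0, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 20.26, 1.0, 1.0, 24.68, 1.0, 1.0,
  1.0, 33.6, 1.0, 1.0, 1.0, 24.64, 1.0, -7.49, 1.0, -7.49, -7.49, 1.0, 33.6, 1.0, -6.54, 1.0, 1.0, 1.0, 1.0, -7.49,
  13.34, -6.54, 1.0, 1.0, 1.0, -6.54, 1.0, 1.0, 58.28, 1.0, 1.0, 1.0, -1.88, 1.0, 44.94, 44.94, -1.88, 1.0, 24.68, 1.0,
  1.0, 1.0, 1.0, 13.34, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0, 20.26, 1.0, 1.0, 1.0, 33.601, 1.0,
  20.26, -6.54, 1.0, -6.54, -6.54, 20.26, 18.38, 1.0, 1.0, 1.0, 1.0, 1.0, -6.54, 20.26, 20.26, 20.26, 1.0, -1.88, 1.0, 20.26,
  1.0, 20.26, 1.0, 1.0, 33.6, 20.26, 20.26, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 1.0, 44.94, 20.26, 1.0, 1.0, 1.0, 1.0,
  1.0, 1.0, -14.03, 1.0, 1.0, -6.54, 20.26, -7.49, 1.0, 1.0, 1.0, 1.0, 1.0, 13.34, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0,
  -14.03, 1.0, 13.34, 1.0, 1.0, 1.0, 1.0, -9.37, 24.68, 1.0, 13.34, 1.0, 24.68, 1.0, 1.0, 1.0, -14.03, 1.0, 1.0, -7.49,
  24.68, -15.91, 1.0, 24.68, 1.0, 1.0, -6.54, -7.49, 13.34, 1.0, 1.0, 1.0, 44.94, 1.0, 13.34, 1.0, -7.49, -9.37, 13.34, 1.0,
  1.0, 1.0, 1.0, -14.03, 1.0, 1.0, 1.0, -7.49, 1.0, 1.0, 1.0, -1.88, 1.0, 1.0, 20.26, 1.0, -7.49, 1.0, -6.54, 1.0
), nrow = 20, byrow = TRUE, dimnames = list(AA_ORDER, AA_ORDER))
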