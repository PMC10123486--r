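# Case-study data and published table values used across the suite.

proto_sets <- function(prob, col = "prototype") {
  ids <- unique(prob[[col]])
  sets <- lapply(ids, function(id) {
    as_pfset(prob[prob[[col]] == id, c("element", "mu", "nu")])
  })
  names(sets) <- ids
  sets
}

pattern_sets <- function() {
  ex <- pf_example("patterns")
  c(proto_sets(ex$prototypes), list(Q = ex$query))
}

diagnosis_sets <- function() {
  ex <- pf_example("diagnoses")
  c(proto_sets(ex$prototypes), list(Q = ex$query))
}

medicine_sets <- function() {
  med <- pf_example("medicines")
  rows <- proto_sets(
    dplyr::mutate(tibble::as_tibble(med), element = criterion),
    col = "alternative")
  c(rows, list(ideal = pf_ideal(med)))
}

# Published distance tables (4-decimal print). Columns: one per compared
# pair, in case-study order. `verified` flags the measures whose full row
# the registered dialect reproduces; unverified rows (documented known
# discrepancies) are excluded from replication assertions.
table3_printed <- rbind(
  hamming        = c(1.1000, 0.3000, 1.4000),
  euclidean      = c(0.5657, 0.1732, 0.8718),
  norm_hamming   = c(0.3667, 0.1000, 0.4667),
  norm_euclidean = c(0.3266, 0.1000, 0.5033),
  ba_sq1         = c(0.0803, 0.0241, 0.1983),
  ba_sq2         = c(0.2754, 0.1000, 0.3316),
  grzegorzewski  = c(0.3667, 0.1000, 0.4667),
  yang_chiclana  = c(0.3667, 0.1000, 0.4667),
  wang_xin       = c(0.3250, 0.1000, 0.4167),
  jin            = c(0.3667, 0.1000, 0.4667),
  song           = c(0.1112, 0.0229, 0.2005),
  ren            = c(0.4823, 0.1439, 0.5393),
  peng           = c(0.4967, 0.1500, 0.5467),
  ejegwa_awolola = c(0.0903, 0.0687, 0.1146),
  sarkar_biswas  = c(0.4889, 0.1856, 0.4933),
  mahanta_panda  = c(0.5375, 0.1551, 0.5995))
table3_verified <- setdiff(rownames(table3_printed), "sarkar_biswas")

table4_printed <- rbind(
  hamming        = c(0.8000, 2.7000, 2.4000, 1.9000, 2.3000),
  euclidean      = c(0.3317, 1.1225, 1.0392, 0.7874, 0.9539),
  norm_hamming   = c(0.1600, 0.5400, 0.4800, 0.3800, 0.4600),
  norm_euclidean = c(0.1483, 0.5020, 0.4648, 0.3521, 0.4266),
  ba_sq1         = c(0.0070, 0.1748, 0.1500, 0.0607, 0.1000),
  ba_sq2         = c(0.0700, 0.4304, 0.4276, 0.2747, 0.3056),
  grzegorzewski  = c(0.1000, 0.5400, 0.4800, 0.3400, 0.3800),
  yang_chiclana  = c(0.1600, 0.5400, 0.4800, 0.3800, 0.4600),
  wang_xin       = c(0.0900, 0.4900, 0.4550, 0.3100, 0.3450),
  jin            = c(0.1600, 0.5400, 0.4800, 0.3800, 0.4600),
  song           = c(0.0299, 0.1747, 0.1642, 0.0784, 0.1097),
  ren            = c(0.1295, 0.5040, 0.5438, 0.3352, 0.3552),
  peng           = c(0.1280, 0.5440, 0.5680, 0.3700, 0.3760),
  ejegwa_awolola = c(0.0476, 0.0780, 0.0688, 0.1316, 0.0960),
  sarkar_biswas  = c(0.1440, 0.5280, 0.5500, 0.3460, 0.3400),
  mahanta_panda  = c(0.1343, 0.7652, 0.7103, 0.5514, 0.6309))
table4_verified <- setdiff(rownames(table4_printed),
                           c("sarkar_biswas", "ejegwa_awolola"))

table6_printed <- rbind(
  hamming        = c(3.1986, 2.9826, 3.1060, 2.8737, 0.9014, 2.7033),
  euclidean      = c(1.0726, 1.0525, 1.1224, 1.0175, 0.4675, 1.1000),
  norm_hamming   = c(0.3998, 0.3728, 0.3884, 0.3592, 0.1127, 0.3379),
  norm_euclidean = c(0.3792, 0.3721, 0.3968, 0.3597, 0.1653, 0.3889),
  ba_sq1         = c(0.0776, 0.0677, 0.0790, 0.0646, 0.0136, 0.0857),
  ba_sq2         = c(0.2884, 0.2546, 0.2942, 0.2626, 0.0616, 0.2750),
  grzegorzewski  = c(0.4000, 0.3750, 0.3625, 0.3500, 0.1125, 0.3500),
  yang_chiclana  = c(0.4139, 0.3834, 0.3786, 0.3603, 0.1212, 0.3522),
  wang_xin       = c(0.3531, 0.3250, 0.3344, 0.3125, 0.0938, 0.3188),
  jin            = c(0.4069, 0.3781, 0.3834, 0.3598, 0.1169, 0.3450),
  ren            = c(0.3955, 0.3765, 0.4287, 0.3908, 0.1884, 0.4006),
  peng           = c(0.4100, 0.3687, 0.4087, 0.3825, 0.1162, 0.3312),
  mahanta_panda  = c(0.4410, 0.3850, 0.4506, 0.4229, 0.1156, 0.3773))
# song (sign-flipped with two cells transposed in print), ejegwa_awolola
# and sarkar_biswas rows are not reproducible; see the vignette.
table6_verified <- rownames(table6_printed)

random_pair <- function(seed, n = NULL, mode = "pythagorean") {
  if (is.null(n)) n <- 1 + seed %% 5
  list(P = pf_random(n, seed = seed, mode = mode),
       Q = pf_random(n, seed = seed + 10000, mode = mode))
}

# Absolute-tolerance comparison (expect_equal's tolerance is relative).
expect_within <- function(actual, expected, tol, label = NULL) {
  testthat::expect_lt(max(abs(actual - expected)), tol,
                      label = paste(label, "max abs deviation"))
}
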