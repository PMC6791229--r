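# Shared fixtures, built in code.

# Published training counts (2005-2014) and testing counts (2015-2017) of the
# bundled Chinese occupational-disease series.
china_train_counts <- c(12212, 11805, 14296, 13744, 18128,
                        27240, 29879, 27420, 26393, 29972)
china_test_counts <- c(27389, 29838, 25114)

# Reference fitted/forecast table for the five grey models on the Chinese
# series (integer-rounded, 2005-2017).
ref_grey_table <- data.frame(
  year = 2005:2017,
  EGM      = c(12212, 14255, 15805, 17523, 19429, 21541, 23883, 26480, 29359,
               32552, 36091, 40015, 44366),
  EDGM     = c(12212, 14268, 15821, 17543, 19452, 21569, 23917, 26519, 29406,
               32606, 36155, 40089, 44452),
  ODGM     = c(12212, 14136, 15700, 17438, 19368, 21511, 23892, 26536, 29473,
               32735, 36358, 40382, 44851),
  DGM      = c(12212, 14415, 15954, 17658, 19544, 21631, 23941, 26498, 29328,
               32460, 35926, 39763, 44009),
  Verhulst = c(12212, 14677, 17261, 19855, 22345, 24638, 26668, 28404, 29845,
               31012, 32663, 33222, 33649))

# Reference accuracy rows (ME, RMSE, MAE, MPE, MAPE) for the grey fits.
ref_grey_accuracy <- rbind(
  EGM_training      = c(-194.98, 3301.76, 2721.90, -4.14, 13.02),
  EGM_testing       = c(-12710.28, 13539.22, 12710.28, -47.51, 47.51),
  EDGM_training     = c(-222.41, 3303.21, 2729.17, -4.26, 13.07),
  EDGM_testing      = c(-12785.03, 13612.40, 12785.03, -47.79, 47.79),
  ODGM_training     = c(-191.14, 3303.79, 2711.09, -3.99, 12.85),
  ODGM_testing      = c(-13083.32, 13918.45, 13083.32, -48.89, 48.89),
  DGM_training      = c(-255.17, 3305.40, 2748.96, -4.56, 13.32),
  DGM_testing       = c(-12452.21, 13271.52, 12452.21, -46.56, 46.56),
  Verhulst_training = c(-1582.72, 3212.63, 2745.38, -11.26, 15.32),
  Verhulst_testing  = c(-5730.92, 6113.10, 5730.92, -21.53, 21.53))
colnames(ref_grey_accuracy) <- c("ME", "RMSE", "MAE", "MPE", "MAPE")

geom_series <- function(q, r, n, start_year = 2001L) {
  annual_series(start_year + seq_len(n) - 1L, q * r^(seq_len(n) - 1))
}

china_split <- function() split_series(china_occupational())
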