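#!/usr/bin/env Rscript

# Step 2: extract the 17 color and texture parameters for every image.
#
# Each experiment subdirectory of the image root becomes one experiment_id;
# every image yields one row. Settings (binarization thresholds
# 0.05/0.10/0.15/0.20, 8 GLCM brightness classes over the fixed [0, 255]
# range, four symmetric directions) reproduce the published analysis.
#
# Output: results/features.csv

suppressPackageStartupMessages({
  library(optparse)
  library(compostvision)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--images", type = "character", default = "results/synthetic_study"),
  make_option("--out", type = "character", default = "results/features.csv")
)))

features <- extract_features_dir(opts$images, quiet = FALSE)
write_feature_table(features, opts$out)
cat(sprintf("wrote %d feature rows (%d skipped files) to %s\n",
            nrow(features), attr(features, "n_skipped"), opts$out))
cat("\nper-experiment means of selected parameters:\n")
agg <- aggregate(cbind(R_MEAN, GS_MEAN, WH_PERCENT1, ENERGY) ~ experiment_id,
                 data = features, FUN = function(x) round(mean(x), 2))
print(agg, row.names = FALSE)
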