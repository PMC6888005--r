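#!/usr/bin/env Rscript

# Step 1: synthesize the study images.
#
# Emulates the original design: 10 composting experiments, 3 favorable
# (proper thermophilic phase; dark, largely decomposed material) and 7
# unfavorable (brighter material with more undecomposed straw), 32 images
# each. Images are generated at 324 x 484 (half the acquisition
# resolution) to keep the run light; class means and across-image spreads
# follow the published group summary.
#
# Output: results/synthetic_study/<EXPERIMENT>/imgNNN.png, groups.csv,
# generator.yml

suppressPackageStartupMessages({
  library(optparse)
  library(compostvision)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results/synthetic_study")
)))

st <- generate_study(opts$out, seed = opts$seed)
cat(sprintf("wrote %d images into %d experiment directories under %s\n",
            length(st$files), nrow(st$groups), opts$out))
print(st$groups)
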