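#!/usr/bin/env Rscript

# Step 3: compare favorable vs unfavorable groups.
#
# For each of the 17 parameters: group means, sample SDs, two-sided
# Mann-Whitney U p-value (image as the unit of analysis), absolute
# percentage difference relative to the favorable mean, and the counts of
# parameters whose difference exceeds 10/50/100%.
#
# Output: results/report.json (machine-readable, with config echo) and
# results/report.txt (summary-table layout).

suppressPackageStartupMessages({
  library(optparse)
  library(compostvision)
})

opts <- parse_args(OptionParser(option_list = list(
  make_option("--features", type = "character", default = "results/features.csv"),
  make_option("--groups", type = "character",
              default = "results/synthetic_study/groups.csv"),
  make_option("--out", type = "character", default = "results/report.json"),
  make_option("--text", type = "character", default = "results/report.txt")
)))

features <- read_feature_table(opts$features)
groups <- read_groups(opts$groups)
cmp <- summarize_groups(features, groups)
report <- render_report(cmp, json_path = opts$out, text_path = opts$text)

cat(readLines(opts$text), sep = "\n")
cat(sprintf("\nwrote %s and %s\n", opts$out, opts$text))
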