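#!/usr/bin/env Rscript
# Stage 2 — nightly migration traffic.
#
# Converts each station-night's profile into a traffic rate in
# birds/km/night: reflectivity x groundspeed per height bin, trapezoid
# integration over the night, x 0.1 km bin height, summed over bins,
# divided by the 11 cm^2 cross-section of an average migrant. Seasons with
# fewer than 100 complete nights are flagged invalid, mirroring the
# archive-completeness rule used with operational radar data.

suppressMessages({library(aeroalert); library(data.table)})
cfg <- pipeline_config("analysis/config.yaml")
ds <- load_dataset("results/dataset")
nightly <- integrate_profiles(ds$profiles, cfg$cross_section, cfg$bin_height)
fwrite(nightly, "results/nightly.csv", dateTimeAs = "ISO")
seasons <- build_seasons(nightly, cfg$simulation$season, cfg$min_nights)
for (s in seasons) print(s)
cat(sum(vapply(seasons, `[[`, logical(1), "valid")), "of", length(seasons),
    "station-seasons pass the >=", cfg$min_nights, "night filter\n")
cat("nightly traffic written to results/nightly.csv\n")
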