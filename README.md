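# tdbscan

Spatiotemporal density clustering of satellite tracking data for
identifying migratory-bird stopover sites.

## The problem

Satellite tags on migratory birds record a position every one to a few
hours for months or years. Buried in those tracks are the stopover sites —
places where the bird interrupts migration for days to weeks to rest and
refuel — and ecologists need each site's location, arrival date, departure
date and duration. Spatial-only density clustering (DBSCAN) finds the
clumps but, blind to time, fuses every visit to a site across seasons and
years into one cluster and yields no dates.

## The method

`tdbscan()` keeps DBSCAN's spatial radius ε but replaces its
minimum-neighbor count with a dwell-time test. For a fix
*a_i* = (*x_i*, *y_i*, *t_i*):

* **spatial neighborhood** N_ε(a_i): all fixes within ε km great-circle
  (haversine) distance;
* **temporal neighborhood** N_t(a_i): the maximal time-contiguous run of
  N_ε(a_i) containing *a_i* whose consecutive gaps never exceed
  MaxIntervalTime;
* **core fix**: max *t* − min *t* over N_t(a_i) ≥ MinStayTime.

Clusters are the transitive closure of core fixes' temporal
neighborhoods; everything else is noise (flight legs, brief stops). A
revisit separated by more than MaxIntervalTime can never join the earlier
visit's cluster, so each visit — including the same wetland one year
later — becomes its own stopover record.

Two performance devices are built in: a quadtree spatial index for
neighborhood queries (conservative bounding-box pruning + exact haversine
filter, provably result-identical) and convex-hull-guided expansion
(only hull vertices of newly added fixes are re-queried; orders of
magnitude fewer queries on dense clusters, at a bounded ≈1% worst-case
assignment discrepancy). Defaults: ε = 25 km, MinStayTime = 72 h,
MaxIntervalTime = 3 d — suited to large waterbirds on continental
flyways.

The package also ships a classic DBSCAN baseline, clustering-comparison
metrics (Calinski–Harabasz index, recognition difference rate, confusion
report), stopover-site summaries, a seeded synthetic migration-track
simulator with ground truth, CSV/GeoJSON IO, and a command-line
interface.

## Worked example

```r
library(tdbscan)

# a six-stop synthetic migration (stays of 14, 18, 7, 9, 16, 7 days)
sim <- scenario_track("multi_stop_migration", seed = 0)
fit <- tdbscan(sim$track)   # eps 25 km, min_stay 72h, max_interval 3d
fit
#> T-DBSCAN clustering of 707 fixes
#>   eps = 25 km, min_stay = 72h, max_interval = 72h
#>   clusters: 6   core fixes: 63   noise: 26 (3.7%)

summary(fit)
#> 6 stopover site(s):
#>  cluster centroid_lat centroid_lon          arrival        departure
#>        0      30.0028     113.0008 2023-01-01 00:00 2023-01-14 23:53
#>        1      36.4991     109.9970 2023-01-15 15:09 2023-02-02 13:54
#>        2      43.0088     107.0013 2023-02-03 06:11 2023-02-10 06:36
#>        3      49.9956     103.9938 2023-02-10 22:08 2023-02-19 21:49
#>        4      58.0012     100.9922 2023-02-20 13:56 2023-03-08 13:56
#>        5      65.9988      98.0066 2023-03-09 04:35 2023-03-16 02:28
#>  duration_days n_fixes
#>           14.0     133
#>           17.9     176
#>            7.0      66
#>            9.0      83
#>           16.0     153
#>            6.9      70
```

Each row is one stopover: the cluster id, the site centroid, and the
arrival/departure window whose span recovers the planted stay lengths to
within the tag's duty cycle. The 26 noise fixes are the flight legs
between sites. On an interannual revisit of a single site the temporal
test is what separates the method from the baseline:

```r
ia <- scenario_track("interannual_revisit", seed = 0)
tdbscan(ia$track)$n_clusters                   # 2  (one per year's visit)
dbscan_baseline(ia$track, min_pts = 4)$n_clusters  # 1  (years fused)
```

Real data goes through `read_track_csv()` (ISO 8601 timestamps,
lat/lon decimal degrees; invalid rows are dropped and reported), or
through the CLI:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts","tdbscan-cli.R",package="tdbscan"))') \
  cluster --input fixes.csv --eps-km 25 --min-stay 72h --max-interval 3d \
  --output-prefix out
```

which writes `out_labeled.csv`, `out_stopovers.csv`,
`out_stopovers.geojson` and `out_metrics.json`. Subcommands `simulate`,
`evaluate` and `compare` cover the generator, the metrics and the
side-by-side baseline comparison.

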