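# ecpfam

Mining associations between Enzyme Commission (EC) numbers and Pfam
domains by content-based filtering.

## The problem

Structure and sequence databases annotate whole protein chains with
Pfam domains and, where known, with 4-digit EC numbers describing the
reaction they catalyse — but they rarely say *which domain carries which
function*. In multi-domain enzymes the mapping is genuinely ambiguous:
a chain may hold two domains with two different activities, one domain
with several activities, an interface or co-factor pair jointly
providing one activity, or accessory domains with no activity at all.
`ecpfam` deconvolutes these cases statistically, for anyone who needs
domain-level structure–function annotations: it infers which (EC number,
Pfam domain) pairs are genuinely associated from how often they co-occur
on non-redundant protein chain/sequence clusters across four annotation
sources of very different reliability.

## The method

Annotations are first collapsed onto clusters of 100%-identical chains
and sequences (CIDs), so redundant database entries carry no extra
weight. Within each source *i*, every EC number and every Pfam domain is
a binary vector over the source's CIDs, and each co-occurring pair gets
the cosine score

    S_i(ec, d) = |CIDs(ec) ∩ CIDs(d)| / ( sqrt(|CIDs(ec)|) · sqrt(|CIDs(d)|) ),

computed as a product of a row-normalised EC×CID and a column-normalised
CID×Pfam sparse binary matrix. The per-source scores are combined into a
confidence score

    CS(ec, d) = Σ_i w_i S_i(ec, d) / Σ_i w_i ,

with missing scores counted as zero. The weights `w_i` are calibrated by
grid search (0 to 1 in steps of 0.1), maximising the ROC area of curated
positive reference pairs ranked against all remaining candidates; the
acceptance threshold on CS is then chosen by scanning 0 to 1 in steps of
0.01 for the best F-measure on a labelled training split (positives plus
shuffled negative pairs). Associations that fail the 4-digit threshold
but whose 3-digit parent class passes an independently calibrated
3-digit scheme are *rescued* into the final set. Each accepted
association gets per-source hypergeometric upper-tail p-values under
Bonferroni family-wise control, and a quality class: **Gold** (above
threshold, all evaluable p-values significant), **Silver** (above
threshold with a non-significant p-value, or rescued with all p-values
significant) or **Bronze** (the rest). On top of the accepted set the
package mines *obligate tuples* — 2 to 4 domains that always co-occur on
every cluster of a given EC number, the signature of interface or
co-factor catalysis — and annotates enzyme-unannotated entities from
their domain content.

Because the real source databases are release-scale downloads, the
package ships a seeded synthetic-world generator (`world_spec()`,
`generate_world()`) that emulates four sources with planted ground
truth, realistic multi-domain architectures, accessory domains and
per-source annotation noise; every pipeline stage is validated against
it and against independent oracles.

## Worked example

```r
library(ecpfam)

world <- generate_world(world_spec())    # default synthetic study, seed 7
result <- run_pipeline(world$datasets, world$positives, seed = 1515,
                       pfam_names = world$pfam_names)
result
#> == EC-Pfam association mining result ==
#> <level_calibration: 4-digit EC>
#>   weights: SIFTS=0.1, SwissProt=1.0, TrEMBL=0.1, UniRule=0.0  (AUC 0.9757)
#>   threshold 0.01: train F=1.0000, test F=1.0000 (P=1.0000, R=1.0000)
#> <level_calibration: 3-digit EC>
#>   weights: SIFTS=0.1, SwissProt=0.9, TrEMBL=0.0, UniRule=0.1  (AUC 0.9767)
#>   threshold 0.01: train F=1.0000, test F=1.0000 (P=1.0000, R=1.0000)
#> final associations: 460 (431 direct, 29 rescued)
#> quality classes: Gold 144 / Silver 287 / Bronze 29
#> obligate tuples: 3
```

The printout reads as follows: the weight grid search identifies the
noise-free curated source (the SwissProt-like one) as the dominant
evidence stream (weight 1.0, ROC AUC 0.976 against all remaining
candidate pairs); the F-measure scan settles on a confidence threshold
of 0.01, which classifies the held-out reference half perfectly
(F = 1.0); 431 associations pass the threshold directly and 29 more are
rescued through their 3-digit parent class; hypergeometric significance
then grades the final set into 144 Gold, 287 Silver and 29 Bronze
associations, and 3 obligate domain tuples are detected.

Individual associations can be queried by either identifier:

```r
query_associations(result$accepted, "PF00061")[, c("ec", "pfam", "cs", "quality")]
#>         ec    pfam         cs quality
#> 1 1.11.1.1 PF00061 0.94055541    Gold
#> 2 1.29.1.1 PF00061 0.02227177  Silver
#> ...
```

and entities lacking an EC annotation are annotated from their domains
with `annotate_entities()`. A thin command-line front end over the same
functions lives at `inst/cli/ecpfam.R` (subcommands `simulate`,
`run-all`, `query`, `annotate`).

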