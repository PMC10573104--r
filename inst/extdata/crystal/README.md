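# Curated experimental reference structures

The radius-of-gyration validation against experimental S-glutathionylated
proteins needs the curated crystal structures from the Protein Data Bank.
They are not redistributed with the package; with network access, download
them once into this directory:

```sh
for id in 3RHB 1HNL 3FZ9 3D5J 3F3R 5NYN 4PQH 4PQI 3Q19 6SR8 4RI7; do
  curl -sO https://files.rcsb.org/download/${id}.pdb
done
```

Then, for any entry:

```r
library(csgkit)
s <- strip_solvent_ions(get_frame(read_pdb("3F3R.pdb"), 1))
radius_of_gyration(s)  # Angstrom, mass-weighted, all atoms present
```

Reference values (Angstrom, to 0.1): AtGrxC5/3RHB 13.2, hLyso/1HNL 14.3,
PtGrxS12/3FZ9 13.2, ScGrx2/3D5J 13.0, ScTrx1/3F3R 12.4, PtTrxL2.1/5NYN 13.5,
PtGSTL1/4PQH 16.9, PtGSTL3/4PQI 17.1, hGSTO2/3Q19 22.6, PtGSTF1/4RI7 20.7.
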