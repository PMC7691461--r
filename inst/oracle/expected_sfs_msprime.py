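"""Independent expected joint-SFS oracle.

Reads a JSON demography (haplotype sample sizes, diploid sizes, backward
migration matrix, population splits) and writes the branch-mode expected
joint SFS, averaged over replicate ancestries, as JSON. Used only as a
cross-check in the test suite; the package's own engine never calls this.

Usage: python expected_sfs_msprime.py config.json out.json
"""
import json
import sys

import msprime
import numpy as np


def main(cfg_path, out_path):
    with open(cfg_path) as fh:
        cfg = json.load(fh)
    nsam = cfg["nsam"]
    ne = cfg["ne"]
    mig = cfg.get("mig_backward")
    splits = cfg.get("splits", [])
    nreps = int(cfg["nreps"])
    seed = int(cfg["seed"])

    P = len(nsam)
    dem = msprime.Demography()
    for i in range(P):
        dem.add_population(name=f"p{i}", initial_size=ne[i])
    if mig:
        for i in range(P):
            for j in range(P):
                if i != j and mig[i][j] > 0:
                    # msprime: rate lineages move i -> j backward in time
                    dem.set_migration_rate(source=f"p{i}", dest=f"p{j}",
                                           rate=mig[i][j])
    # msprime marks the ancestral side of a split inactive before the split,
    # whereas the package's models let a present-day population carry the
    # merged pool; map each merge onto a fresh msprime ancestral population.
    # (Migration among survivors past the first split is not carried over;
    # the cross-check demographies have no such epoch.)
    slot = {i: f"p{i}" for i in range(P)}
    for k, sp in enumerate(sorted(splits, key=lambda s: s["time"])):
        anc_ne = sp.get("ancestral_ne") or ne[sp["ancestral"]]
        name = f"anc{k}"
        dem.add_population(name=name, initial_size=anc_ne)
        dem.add_population_split(time=sp["time"],
                                 derived=[slot[sp["ancestral"]],
                                          slot[sp["derived"]]],
                                 ancestral=name)
        slot[sp["ancestral"]] = name
    dem.sort_events()

    # ploidy=2 keeps msprime on the diploid coalescent time scale (pair rate
    # 1/(2N)), matching the package's diploid Ne; haplotype counts must be even
    if any(n % 2 for n in nsam):
        raise ValueError("haplotype sample sizes must be even")
    samples = {f"p{i}": nsam[i] // 2 for i in range(P) if nsam[i] > 0}
    dims = [n + 1 for n in nsam if n > 0]
    acc = np.zeros(dims)
    reps = msprime.sim_ancestry(samples=samples, demography=dem, ploidy=2,
                                num_replicates=nreps, random_seed=seed)
    for ts in reps:
        sets = [ts.samples(population=i) for i in range(P) if nsam[i] > 0]
        afs = ts.allele_frequency_spectrum(sample_sets=sets, mode="branch",
                                           polarised=True,
                                           span_normalise=False)
        acc += afs
    acc /= nreps
    # proportions over polymorphic classes (drop the two corners)
    flat = acc.reshape(-1, order="F")
    flat[0] = 0.0
    flat[-1] = 0.0
    tot = flat.sum()
    if tot > 0:
        flat = flat / tot
    with open(out_path, "w") as fh:
        json.dump({"dims": dims, "sfs": flat.tolist()}, fh)


if __name__ == "__main__":
    main(sys.argv[1], sys.argv[2])
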