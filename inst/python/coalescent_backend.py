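"""Coalescent backend for popbaseline.

Reads a batch request (JSON) describing a demographic model and a set of
regions, simulates every (region, replicate) with msprime, and writes a plain
text block stream:

    #PANEL
    <population label per haplotype, space separated>
    #REP <region_id> <replicate> <n_sites> <n_haplotypes>
    <site positions, space separated integers (bp)>
    <one 0/1 string per haplotype>

Mutations use the binary 0/1 model so alleles are ancestral/derived
indicators; only sites segregating among the sampled haplotypes are emitted.
All model semantics (event compilation, seeding) are decided by the R caller;
this script only executes the request.

Usage:
    python coalescent_backend.py REQUEST_JSON OUTPUT_TXT
    python coalescent_backend.py --server

In server mode, lines of the form "REQUEST_JSON\tOUTPUT_TXT" are read from
stdin and answered with "DONE" (or "ERR <message>") on stdout, which lets a
caller amortize interpreter start-up over many batches.
"""

import json
import sys

import msprime
import numpy as np


def build_demography(req):
    dem = msprime.Demography()
    for p in req["populations"]:
        dem.add_population(
            name=p["name"],
            initial_size=p["initial_size"],
            growth_rate=p.get("growth_rate", 0.0),
        )
    for mr in req.get("initial_migration", []):
        if mr["rate"] > 0:
            dem.set_symmetric_migration_rate(mr["pops"], mr["rate"])
    for ev in req.get("events", []):
        t = ev["time"]
        if ev["type"] == "size":
            dem.add_population_parameters_change(
                time=t,
                population=ev["pop"],
                initial_size=ev["size"],
                growth_rate=ev.get("growth_rate", 0.0),
            )
        elif ev["type"] == "split":
            # mass migration keeps all populations formally alive, which lets
            # sampled populations persist to time 0 regardless of topology
            dem.add_mass_migration(
                time=t, source=ev["pop"], dest=ev["ancestral"], proportion=1.0
            )
        elif ev["type"] == "migration":
            dem.add_symmetric_migration_rate_change(
                time=t, populations=ev["pops"], rate=ev["rate"]
            )
        else:
            raise ValueError("unknown event type: %r" % ev["type"])
    dem.sort_events()
    return dem


def rate_or_map(spec):
    if isinstance(spec, dict):
        # length-1 vectors arrive as JSON scalars
        return msprime.RateMap(
            position=np.atleast_1d(spec["position"]).astype(float),
            rate=np.atleast_1d(spec["rate"]).astype(float),
        )
    return float(spec)


def process(request_path, output_path):
    with open(request_path) as fh:
        req = json.load(fh)
    dem = build_demography(req)
    sample_sets = [
        msprime.SampleSet(num_samples=int(n), population=name)
        for name, n in req["samples"].items()
        if int(n) > 0
    ]
    hap_pops = []
    for name, n in req["samples"].items():
        hap_pops.extend([name] * (2 * int(n)))
    n_hap = len(hap_pops)

    with open(output_path, "w") as out:
        out.write("#PANEL\n")
        out.write(" ".join(hap_pops) + "\n")
        for region in req["regions"]:
            L = float(region["length"])
            rec = rate_or_map(region["rec"])
            mu = rate_or_map(region["mu"])
            seeds = region["seeds"]
            # replicate ancestries come from msprime's reproducible replicate
            # stream keyed on the region's first seed; mutations are seeded
            # per replicate
            reps = msprime.sim_ancestry(
                samples=sample_sets,
                demography=dem,
                sequence_length=L,
                recombination_rate=rec,
                ploidy=2,
                random_seed=int(seeds[0]),
                num_replicates=len(seeds),
                discrete_genome=True,
            )
            for j, ts in enumerate(reps):
                seed = seeds[j]
                mts = msprime.sim_mutations(
                    ts,
                    rate=mu,
                    random_seed=(int(seed) + 1000000007) % (2**31 - 1) + 1,
                    model=msprime.BinaryMutationModel(),
                    discrete_genome=True,
                )
                # binary model: ancestral allele "0" is always index 0, the
                # derived allele "1" index 1, so genotype values are derived
                # indicators directly
                G = mts.genotype_matrix()
                if G.size:
                    counts = G.sum(axis=1)
                    keep = (counts > 0) & (counts < n_hap)
                    positions = mts.tables.sites.position[keep].astype(int)
                    A = G[keep, :]
                else:
                    positions = np.empty(0, dtype=int)
                    A = np.empty((0, n_hap), dtype=np.int8)
                out.write(
                    "#REP %s %d %d %d\n"
                    % (region["id"], j + 1, len(positions), n_hap)
                )
                out.write(" ".join(str(p) for p in positions) + "\n")
                if A.shape[0] > 0:
                    chars = (A.T + ord("0")).astype(np.uint8).tobytes()
                    S = A.shape[0]
                    for h in range(n_hap):
                        out.write(
                            chars[h * S:(h + 1) * S].decode("ascii")
                        )
                        out.write("\n")
                else:
                    out.write("\n" * n_hap)


def serve():
    for line in sys.stdin:
        line = line.strip()
        if not line or line == "QUIT":
            break
        try:
            req_path, out_path = line.split("\t")
            process(req_path, out_path)
            sys.stdout.write("DONE\n")
        except Exception as exc:  # report and keep serving
            sys.stdout.write("ERR %s\n" % str(exc).replace("\n", " "))
        sys.stdout.flush()


def main():
    if sys.argv[1] == "--server":
        serve()
    else:
        process(sys.argv[1], sys.argv[2])


if __name__ == "__main__":
    main()
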