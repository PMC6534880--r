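"""Chemistry/ML worker process for the smilesrl R package.

Speaks newline-delimited JSON over a localhost socket (default) or over
stdin/stdout with --oneshot.  Each request is {"op": ..., ...}; each
response is {"ok": true, "value": ...} or {"ok": false, "error": ...}.
The R side owns all randomness except where a seed is passed explicitly.
"""

import json
import socket
import sys

import numpy as np
from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, Crippen, Descriptors, rdMolDescriptors
from rdkit.Chem.Scaffolds import MurckoScaffold

RDLogger.DisableLog("rdApp.*")

FURAN = Chem.MolFromSmarts("c1ccoc1")
BENZENE = Chem.MolFromSmarts("c1ccccc1")


def _mol(smiles):
    if smiles is None:
        return None
    return Chem.MolFromSmiles(smiles)


def op_parse(req):
    valid, canonical = [], []
    for s in req["smiles"]:
        m = _mol(s)
        # an empty string parses to an atom-less Mol; not a molecule here
        ok = m is not None and m.GetNumAtoms() > 0
        valid.append(ok)
        canonical.append(Chem.MolToSmiles(m) if ok else None)
    return {"valid": valid, "canonical": canonical}


def op_ecfp6(req):
    nbits = int(req.get("nbits", 4096))
    radius = int(req.get("radius", 3))
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
        else:
            fp = AllChem.GetMorganFingerprintAsBitVect(m, radius, nBits=nbits)
            out.append(sorted(fp.GetOnBits()))
    return out


def op_match_smarts(req):
    patt = Chem.MolFromSmarts(req["smarts"])
    if patt is None:
        raise ValueError("bad SMARTS: %s" % req["smarts"])
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        out.append(bool(m is not None and m.HasSubstructMatch(patt)))
    return out


def _has_fused_ring(mol):
    rings = mol.GetRingInfo().BondRings()
    for i in range(len(rings)):
        for j in range(i + 1, len(rings)):
            if set(rings[i]) & set(rings[j]):
                return True
    return False


def op_substructure(req):
    furan, benzene, fused = [], [], []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            furan.append(None); benzene.append(None); fused.append(None)
        else:
            furan.append(m.HasSubstructMatch(FURAN))
            benzene.append(m.HasSubstructMatch(BENZENE))
            fused.append(_has_fused_ring(m))
    return {"furan": furan, "benzene": benzene, "fused": fused}


# 19 physicochemical descriptors; order must match R side (physchem_names)
def _physchem_one(m):
    return [
        Crippen.MolLogP(m),
        Descriptors.MolWt(m),
        rdMolDescriptors.CalcNumHBD(m),
        rdMolDescriptors.CalcNumHBA(m),
        rdMolDescriptors.CalcNumRotatableBonds(m),
        rdMolDescriptors.CalcNumAliphaticRings(m),
        rdMolDescriptors.CalcNumAromaticRings(m),
        rdMolDescriptors.CalcNumHeterocycles(m),
        rdMolDescriptors.CalcTPSA(m),
        Crippen.MolMR(m),
        rdMolDescriptors.CalcFractionCSP3(m),
        rdMolDescriptors.CalcNumAmideBonds(m),
        rdMolDescriptors.CalcNumBridgeheadAtoms(m),
        rdMolDescriptors.CalcNumHeteroatoms(m),
        m.GetNumHeavyAtoms(),
        rdMolDescriptors.CalcNumSpiroAtoms(m),
        rdMolDescriptors.CalcNumRings(m),
        rdMolDescriptors.CalcNumSaturatedRings(m),
        Descriptors.NumValenceElectrons(m),
    ]


def op_physchem(req):
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            raise ValueError("invalid SMILES: %s" % s)
        out.append(_physchem_one(m))
    return out


def op_scaffold(req):
    mode = req.get("mode", "murcko")
    out = []
    for s in req["smiles"]:
        m = _mol(s)
        if m is None:
            out.append(None)
            continue
        sc = MurckoScaffold.GetScaffoldForMol(m)
        if mode == "generic":
            sc = MurckoScaffold.MakeScaffoldGeneric(sc)
        out.append(Chem.MolToSmiles(sc))
    return out


def _bits_to_dense(bits, nbits):
    X = np.zeros((len(bits), nbits), dtype=np.float32)
    for i, b in enumerate(bits):
        if b:
            X[i, np.asarray(b, dtype=np.int64)] = 1.0
    return X


def op_sk_fit(req):
    from joblib import dump

    X = _bits_to_dense(req["bits"], int(req["nbits"]))
    y = np.asarray(req["y"], dtype=np.int64)
    algorithm = req["algorithm"]
    seed = int(req.get("seed", 0))
    params = req.get("params", {}) or {}
    extra = {}
    if algorithm == "RF":
        from sklearn.ensemble import RandomForestClassifier

        clf = RandomForestClassifier(
            n_estimators=int(params.get("n_trees", 1000)),
            criterion=params.get("criterion", "gini"),
            n_jobs=1,
            random_state=seed,
        )
        clf.fit(X, y)
    elif algorithm == "SVM":
        from sklearn.model_selection import GridSearchCV, StratifiedKFold
        from sklearn.svm import SVC

        grid = {
            "C": [float(v) for v in params["c_grid"]],
            "gamma": [float(v) for v in params["gamma_grid"]],
        }
        inner = StratifiedKFold(
            n_splits=int(params.get("inner_folds", 3)), shuffle=True,
            random_state=seed)
        search = GridSearchCV(
            SVC(kernel="rbf"), grid, scoring="roc_auc", cv=inner, n_jobs=1)
        search.fit(X, y)
        clf = SVC(kernel="rbf", probability=True, random_state=seed,
                  **search.best_params_)
        clf.fit(X, y)
        extra["best_params"] = {k: float(v)
                                for k, v in search.best_params_.items()}
    elif algorithm == "NB":
        from sklearn.naive_bayes import BernoulliNB

        clf = BernoulliNB()
        clf.fit(X, y)
    else:
        raise ValueError("unknown algorithm: %s" % algorithm)
    dump(clf, req["path"])
    extra["path"] = req["path"]
    extra["classes"] = [int(c) for c in clf.classes_]
    return extra


def op_sk_predict(req):
    from joblib import load

    clf = load(req["path"])
    X = _bits_to_dense(req["bits"], int(req["nbits"]))
    prob = clf.predict_proba(X)
    pos = int(np.where(clf.classes_ == 1)[0][0])
    return [float(p) for p in prob[:, pos]]


def op_tsne(req):
    from sklearn.manifold import TSNE

    X = np.asarray(req["x"], dtype=np.float64)
    perplexity = float(req.get("perplexity", 30.0))
    perplexity = min(perplexity, (X.shape[0] - 1) / 3.0)
    ts = TSNE(n_components=2, random_state=int(req.get("seed", 0)),
              perplexity=perplexity, init="pca")
    return [[float(a), float(b)] for a, b in ts.fit_transform(X)]


OPS = {
    "parse": op_parse,
    "ecfp6": op_ecfp6,
    "match_smarts": op_match_smarts,
    "substructure": op_substructure,
    "physchem": op_physchem,
    "scaffold": op_scaffold,
    "sk_fit": op_sk_fit,
    "sk_predict": op_sk_predict,
    "tsne": op_tsne,
    "ping": lambda req: "pong",
}


def handle(line):
    try:
        req = json.loads(line)
        op = req.get("op")
        if op == "shutdown":
            return None
        return json.dumps({"ok": True, "value": OPS[op](req)})
    except Exception as exc:  # noqa: BLE001 - report everything to R
        return json.dumps({"ok": False, "error": "%s: %s"
                           % (type(exc).__name__, exc)})


def serve_socket(portfile):
    srv = socket.socket(socket.AF_INET, socket.SOCK_STREAM)
    srv.bind(("127.0.0.1", 0))
    srv.listen(1)
    with open(portfile, "w") as fh:
        fh.write("%d\n" % srv.getsockname()[1])
    conn, _ = srv.accept()
    f = conn.makefile("rw", encoding="utf-8")
    for line in f:
        resp = handle(line)
        if resp is None:
            break
        f.write(resp + "\n")
        f.flush()
    conn.close()


def serve_stdio():
    for line in sys.stdin:
        if not line.strip():
            continue
        resp = handle(line)
        if resp is None:
            break
        sys.stdout.write(resp + "\n")
        sys.stdout.flush()


if __name__ == "__main__":
    if "--oneshot" in sys.argv:
        serve_stdio()
    else:
        serve_socket(sys.argv[1])
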