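>CYP_domain_consensus_synthetic length=463
MPLLREMSTAQFVTVTYSIGEVMCKYDTKLVDEDNVPMKDLLQVSVLSARDPVATDFVGS
LHSIFDDRGITHPMGEIGNCKHEENQDQNDVSTMTGQNLAGNEPTCASERIASPTRRGNV
VTLYERMRNQSPASDSGVTWGYMTQELTFGNHFNKLVNKIKHEEELDSVPAKIKAVAPTS
NTVSRLFGNSGILFEIKQDETPREESTGADMRRKALKLGGRGETWAPLSFLCCKAKQMQG
LGEKPSNPVICYSAVVAKSPNNVPANLSNRFNQSKKIASSHGLDAGHDTSEENSFKSQRL
QLFAHDGLFPYEASLKVRLLVALPEAVLHHSILAGLFVQGVQDAQTDEAEALRSVSWYDF
STSTEDRIAKNEIDMPALMYSTLVVTHSKGGLEYAGLKGYFLAPDATFIPERFAIGTAVE
TALSLIGANPFGAGRRICAGATLSHFIPDIRPYDRNAKAWFKL
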