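>Rn-rhodopsin-synthetic
MNGTEGPNFYVPFSNKTGVVRSPFEAPQYYLAEPWQFSMLAAYMFLLIMLGFPINFLTLY
VTVQHKKLRTPLNYILLNLAVADLFMVFGGFTTTLYTSLHGYFVFGPTGCNLEGFFATLG
GEIALWSLVVLAIERYVVVCKPMSNFRFGENHAIMGVAFTWVMALACAAPPLVGWSRYIP
EGMQCSCGIDYYTPHEETNNESFVIYMFVVHFIIPLIVIFFCYGQLVFTVKEAAAQQQES
ATTQKAEKEVTRMVIIMVIAFLICWLPYAGVAFYIFTHQGSDFGPIFMTIPAFFAKTSAV
YNPVIYIMMNKQFRNCMVTTLCCGKNPLGDDEASTTVSKTETSQVAPA
>Sp-opsin_1
EDLYCWMCNAIKIFQMVGIEGPHEYGPNSNKTKVRRSPFEAFGYDQAEPWQLSMLAAYMF
LLVSVQQPINFMDLCVGVQHKNKGTRLMFLLLHGNVADKHAVFGHYVKFLYTSCHGVFTF
GPTKCNLEHFFRTLGGEIALWSTHVCTIERYHICCYQMSNFRFGDNHAIDGNAFTAVMDL
HCPKPHPVGWCRHIPEIMQKSCPQTYYPPHWETNNHSFPWDTFVVHFEPPLQVIFTCHGQ
RVFTSAEYAAQQMESATTLKAEKGVTRMVIWMVTIKLVCWLPYAGLAFVIFTCQGDDFGF
ILMTIPAFIAKHTAVYNPVIYIMMNKQFYNCMVTTLCCEKIGLGDDLMSTDVEKIYTSWV
PPKSSEKEAHTLYENHQGAYHCNSYLTHDDGQTWKVML
>Sp-opsin_2
DESKGKVTGMTEGPKFYVGMSDKTHDVKLPFEAFCYYLQCPLQVGLLPAKYFLLIMLGFA
ICKLRLAQTWQHKKLMTPVHYILLDLAVAFLFMKFGTFNTHLYTSLSGYFVAGPHACNRE
GFFATAGGEAALRSKVVKAIERYNVYAQPNSNFHFCMRHVIMTVAFTEGMALAIAAEPLW
GWERYIPEETHGSCHHDHWTYHCETINESCVIYNFPVHEIIPLIVIFVIYWKLFFIDKNA
AADQQWKCTTQLAEKEIFECVHIMVLAGGFMIGPYAGVAVYIFTHQGYDFGPIYMTIPAF
RAKTSADYNPVIYIMMSGTFKNQMVETLCCGKNFLGEDEVSQMGRKHETSQVAAHCRDET
L
>Sp-opsin_3.1
GFHVLMVGTEAPNFYVPFSNKQKIVRSLFKAPQYYDAEVSNFFYLAAYMFLLITLGFPTN
ELTGYSTGQHMKIRLPLNYILWSLCDADLFMVFTGQTTASYTENLGYMVFIPAVCNMYGP
FASLPGEIKLWPMVVLAIERYPAVCGGCTNFRFGSFHKILGVAFEWVGAPAQALYPLVAW
SRYYQEGMQCSCYIVHYTSHDGTEYYTFVIPMFVYHIIIPLITIFFYYGGWVHTVPEWMR
QQEESASKQKAETENTRMMEMMVETFLMAWLPEAGVAFYIFIYQGHDFGPIGMTIPAFFA
KTIASYNPVIYIMMNKQFRNVWVTTLCCGKNPKGRMEASAVWSKMCTAQVAPALRVDK
>Sp-opsin_3.2
MVGTIAPNFYLPFSNKQKIVNSLFKAIQYYPVEVTNTFYLAAYMFLLITLGFPTNELTWY
VTGQHMKIRQPLNYILWSLCDADLFMVFTGQTTASYTENLGYFVFGPAGCNMYGPFASLP
GEIKLWPMVVLAIERYIDVQKGCSNFRFGEFHKILGVASTWVGALAQALYPLVAITRYYQ
EGMQCSCSIVHYTSHDGTEYGAFVIMMFVYHIIIPLIVIFFYQGGLVETVPEAMRQQQES
ATKHKAETENTRMFEMMVEAFLIAWLPEAGVEFYIFTYQGHDFGPIGMTKPAFFAKTIAS
YNPVIYIMMNKQFRNVMVTTLCCGKNPKGRMEASKVWSKMCTSQVAPALDNGLY
>Sp-opsin_4
MQATCEAMVHTEGRNFYVSFSNKTFVVRHTMWAPQYISAAMWHFCELAAYHFTWIFKAFP
INVDLLWVTVQHIKLRTALIYILYNLAYLDLRYVFGGGEQFLYESFRQYEVCGPVGCWFY
GHSVTLCGEIFLWYLVVLEIERYVTVCDPMSNFRFMENHAYMRVMFTWVMALAGIAETLV
GWSRYIPEVMQWHCGIDYDTYHEETPNESFDNHMAHDHFTIPLIVIFFCYTCIVFTVKEI
AAQAHPSATIKKLPKELTRWVQIMHMEFLICDLPTAGVAFYCFTYWGCVFAPIFMTIFAF
SAKTSASVNPVIYIMMHPKFRECPPITNCCGHAKLYDDESNYVVSLTQTRTVAPKEM
>Sp-opsin_5
MEGMSGTEGPLEYYPFSNKTGVVRNPFEAPKVNLAETWQFSGLAATMFLLAMLGFMINFS
LLYVPDPAKRKHTPLRYGLLNLAVSDLVMVFYGHTYLLYTSLHGLFASGPNGCALEGFFA
TLPGEWANWSLVSLAMERYFVVCKPTSNFRFGENHAIMGVAFTWVMAGACAAPNLEGWSR
HIREGMSCCCGIDRGCPDEETNPESFVMNMKVNDLNIPLKVIFGCCPALVDPVEENAAWA
QESKTGQKAEKWVTDMVIIHHIAFLICYWPHAGQATKIFPHQSSDLGPIFMTIPRFFAKT
SAVENPVIYIMMNKQFGKCMMTTLCCGLNILGRDAASTTVPSTETLFVAMAGFLVGPAY
>Sp-opsin_6
KIMIDMNNGTSGIGFYVPFEQKTGVDRVPFEAPQYYLAEPWQFFMLMAYMRLCIMLGFQI
NFLTLCITVILKKLRTGLNAILLNLAKMDLDSVFVGWTMTLLTSLHGYFVFIIAVCNPEV
FAANLGGELAWWSLVVLAIERYSLVCKPYSNFFFKPNHYIDGVECTWVKAAACAHPYLAG
WSREISESMGQSCGTDYQTFQRESNAETFVIYMFVVHKHWPLIVQFHCYGPLVYAEKEYA
VQRQECARTQMVTDGVTRMCIRMVIGFLICWLPNHITYFYIFHHQGSDQVPIFITIPAFF
ASTSAVFNPVIYIMMAGTFDHMMVTWLCCNKNFNGDDEAQTLVSCEWTAGVAVAKAAN
>Sp-opsin_7
DNHMVMFNCEVPFFNKHPRVDSPFEAPQNYLGGDWMFSMLAPYMYLLIMLGFPIFCLQLY
VTMLHDALRTVCNYILLNLAGDQPVMVFGEFTDRLYTSLHGYFVFGPTGCNLYDFFFTLG
GEAFVESLVVCAIERYWVSCKPMSPFIFHENHFMMDVAFTWVMAFACAPPPLDHWSRYIK
EVMQIICGISFVTPTVETNNESFVCYMFPVHLGLALIVKFFMYGQLKFFVTEAAAQQQDS
ATTQFPCHEVIKMVDATVIARLQCWWEYNGVSFYIKNNQCSKFQPIFMHIPLMFAKTDAV
HNPVIYIMMGSTFRNGMVTTTCCGKNPLGDDEASLTRSKTETSQVAPW
>Sp-opsin_8
GYAVMLGLEGPWFYVPRSNKTPVVCSHCQAKQYYLAEPFQFSMLWPYMALCIMLQFPINF
LTLYVPVVHHKFRMPLYYIFNNLAVSYLFMRFGCPTTTLRFSLHGYFVQGKTGCNLECYS
ATLGGEIALWSNWVTKLERYMVVVTSCAQFWFGCNHAKMGVADTWVMRLDCRAQLLVQYI
RYIEEEMSMSCGRVYWTGVEHTYNELKVISMFVVHTAIPVCYIFSCYTQLVFFPKQAANQ
QCESATTRKDCERDTRMTSIAVIAKLCIWLPYAGVAFYIFPHKYSDFGAFEMTIIAFFAK
TRAVYNPVIYIMMNKQFRCCMVTIYCCGKNPLTFDEVWTYSPELETSQIDPADCSVFLM
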