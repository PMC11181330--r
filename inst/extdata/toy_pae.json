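{"predicted_aligned_error":[[0,6.96765105240047,8.69575145281851,0.596600158768706,6.63288531638682,0.49673865144141,5.99805576726794,6.9866496482864,0.321106431330554,0.448446214897558,8.39274446107447,0.459163866774179,0.398534086975269,0.548948729457334,0.454077557497658,5.4859987385571,8.82081050705165,5.28297087084502,8.41383729502559,6.01540909800678],[6.96765105240047,0,8.99578315392137,8.53352311067283,0.584208610793576,8.74195532687008,8.47847764473408,0.582843618979678,8.39304803777486,0.523229275317863,8.60849132295698,5.81140942219645,0.445536503638141,7.78980317059904,6.59383738413453,8.47760859224945,7.70679114386439,0.32531803662423,5.69525571260601,8.46787396911532],[8.69575145281851,8.99578315392137,0,7.30303714051843,7.24267087411135,8.00229072291404,7.39062909316272,7.64002827182412,0.576725276000798,8.41343209985644,0.466114329057746,7.37130304891616,7.7550565013662,8.37750701326877,6.01079968549311,8.96826252434403,5.52064357232302,0.464111873321235,6.87312697339803,0.460830740723759],[0.596600158768706,8.53352311067283,7.30303714051843,0,6.99932785890996,7.6991042168811,0.534703891910613,6.27445134520531,8.26270152255893,0.577460280689411,0.528237805981189,0.388494320958853,0.500439828517847,5.31547217722982,6.33804973401129,7.9049826702103,0.300707959569991,0.419477051356807,0.356878401827998,0.59480911125429],[6.63288531638682,0.584208610793576,7.24267087411135,6.99932785890996,0,6.98873910773546,7.46255563758314,8.26870267186314,6.46071210503578,8.63040317967534,8.8561387648806,0.530110586201772,8.58440740872175,5.26841324288398,5.0472968807444,7.80191790126264,5.37248946726322,6.30967304389924,0.423616545181721,8.41529176291078],[0.49673865144141,8.74195532687008,8.00229072291404,7.6991042168811,6.98873910773546,0,7.40313316509128,5.44165422394872,6.59310648590326,7.19331083446741,7.75320108607411,8.16799143981189,5.3410247983411,6.20590044651181,5.52701463829726,6.92240041773766,8.83708059228957,6.93532294500619,0.533170769736171,0.441186526254751],[5.99805576726794,8.47847764473408,7.39062909316272,0.534703891910613,7.46255563758314,7.40313316509128,0,8.30567610450089,8.56150008086115,0.403812658810057,0.440307935234159,5.90392103791237,6.61043963767588,5.25387628842145,5.38707086630166,7.15403931308538,6.72751065529883,0.451353630702943,0.432136539369822,0.507160476548597],[6.9866496482864,0.582843618979678,7.64002827182412,6.27445134520531,8.26870267186314,5.44165422394872,8.30567610450089,0,6.72750480379909,6.56468700990081,6.4253281224519,7.71845152042806,7.41603517252952,0.362757042632438,7.95879758428782,8.88524186611176,5.15306498482823,5.68804564420134,5.68330899626017,0.489017438795418],[0.321106431330554,8.39304803777486,0.576725276000798,8.26270152255893,6.46071210503578,6.59310648590326,8.56150008086115,6.72750480379909,0,5.49581663031131,6.81208821944892,7.85627328790724,5.63954308070242,0.408164611668326,6.83281116001308,6.60737223550677,7.0453624855727,7.25214021094143,7.43047412578017,5.6022181250155],[0.448446214897558,0.523229275317863,8.41343209985644,0.577460280689411,8.63040317967534,7.19331083446741,0.403812658810057,6.56468700990081,5.49581663031131,0,8.90833464544266,6.68756476510316,0.311081667803228,0.420162218017504,8.95682287868112,0.591345197358169,5.25627476163208,0.50337293073535,8.75863208062947,0.493261402007192],[8.39274446107447,8.60849132295698,0.466114329057746,0.528237805981189,8.8561387648806,7.75320108607411,0.440307935234159,6.4253281224519,6.81208821944892,8.90833464544266,0,7.62905215844512,7.13622402492911,0.48958260754589,0.312323530716822,5.0273936027661,8.88528553210199,0.561586163635366,0.387459045625292,8.44484702590853],[0.459163866774179,5.81140942219645,7.37130304891616,0.388494320958853,0.530110586201772,8.16799143981189,5.90392103791237,7.71845152042806,7.85627328790724,6.68756476510316,7.62905215844512,0,8.38124532159418,5.08606849517673,0.332353204325773,0.304687989642844,8.96001979801804,8.10368058085442,8.33269202243537,0.554317329078913],[0.398534086975269,0.445536503638141,7.7550565013662,0.500439828517847,8.58440740872175,5.3410247983411,6.61043963767588,7.41603517252952,5.63954308070242,0.311081667803228,7.13622402492911,8.38124532159418,0,7.86684857681394,5.12990403082222,0.412359136878513,8.1946622133255,0.365997866308317,7.89968855679035,7.02991014905274],[0.548948729457334,7.78980317059904,8.37750701326877,5.31547217722982,5.26841324288398,6.20590044651181,5.25387628842145,0.362757042632438,0.408164611668326,0.420162218017504,0.48958260754589,5.08606849517673,7.86684857681394,0,8.43122087325901,8.73734605684876,0.518439370254055,5.17815179098397,6.50148288719356,7.16762306727469],[0.454077557497658,6.59383738413453,6.01079968549311,6.33804973401129,5.0472968807444,5.52701463829726,5.38707086630166,7.95879758428782,6.83281116001308,8.95682287868112,0.312323530716822,0.332353204325773,5.12990403082222,8.43122087325901,0,8.49835230968893,7.17770751193166,5.95621152408421,7.59409661497921,6.71600968297571],[5.4859987385571,8.47760859224945,8.96826252434403,7.9049826702103,7.80191790126264,6.92240041773766,7.15403931308538,8.88524186611176,6.60737223550677,0.591345197358169,5.0273936027661,0.304687989642844,0.412359136878513,8.73734605684876,8.49835230968893,0,7.57231797184795,8.39658657182008,5.1798946140334,7.58071847539395],[8.82081050705165,7.70679114386439,5.52064357232302,0.300707959569991,5.37248946726322,8.83708059228957,6.72751065529883,5.15306498482823,7.0453624855727,5.25627476163208,8.88528553210199,8.96001979801804,8.1946622133255,0.518439370254055,7.17770751193166,7.57231797184795,0,7.43012836389244,7.08410194609314,0.324716018512845],[5.28297087084502,0.32531803662423,0.464111873321235,0.419477051356807,6.30967304389924,6.93532294500619,0.451353630702943,5.68804564420134,7.25214021094143,0.50337293073535,0.561586163635366,8.10368058085442,0.365997866308317,5.17815179098397,5.95621152408421,8.39658657182008,7.43012836389244,0,6.58444323390722,6.18127569463104],[8.41383729502559,5.69525571260601,6.87312697339803,0.356878401827998,0.423616545181721,0.533170769736171,0.432136539369822,5.68330899626017,7.43047412578017,8.75863208062947,0.387459045625292,8.33269202243537,7.89968855679035,6.50148288719356,7.59409661497921,5.1798946140334,7.08410194609314,6.58444323390722,0,8.36900318600237],[6.01540909800678,8.46787396911532,0.460830740723759,0.59480911125429,8.41529176291078,0.441186526254751,0.507160476548597,0.489017438795418,5.6022181250155,0.493261402007192,8.44484702590853,0.554317329078913,7.02991014905274,7.16762306727469,6.71600968297571,7.58071847539395,0.324716018512845,6.18127569463104,8.36900318600237,0]],"max_predicted_aligned_error":31.75}
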