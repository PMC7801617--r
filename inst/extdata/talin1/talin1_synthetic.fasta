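>TLN1_SYNTHETIC synthetic stand-in for human talin-1 (2541 aa); key residues pinned
GVGQAGELLIFGGATERPPKLVQKWHIDTNITDGALRVLPSFRAMSHRLMVTNSGGWSICTCRLGFKAIY
DVRGDANGDPADQKAKCRPAHDMIFNENDSAFVMSKDHSLLPVETREHPVELTISQLHSIPVIVTEGPHT
QIFPSVFLLVYYDFIHIQDDVPADRKLNIADRGLKITERIKSFFTDVLVRKGEVTAFKPGTTGEIDFAGP
PPIEQHATHARMSGAVYVPILSNNAHKITVMRVEQVGILRPKNHTSLNASNGAEERRVRIAQEKVGRIKK
VMMAWPKLTDLRFRFFTSDRSTLGVDLEVSKREFFPLDAISQEKVCAHCVCAEIPPDELSNQSDTNVRAH
TAGFLDTDNRPYDGEAIFERATEKMLAASELSHGFEGEADAISRFLIDAVIMAKVEDRNLLNLPDAAPAK
VRCRNLSATLDLKKTITTSPSNARKASEFMFYQGINRASGDNGKIDGLTTMREKFPAYKKPPALENFPNI
NAKDSITASPIRPQMVLYMWMDRFRGLLAARKSGLLDFVLGQLMVQQQARHHSHSRVEEILTSKKGQPRA
KPLMNDKFPCAFNELAVSQNLAPAISAGTHPDFEAKIELHEPIGSEHTNGEYSFIHMSRYPHPQGLTVAE
AKPIVNESDYRNHSNYDGRAGYMTSVASKAKPLQLKGISFDRLKEIMCRSDAYMFDPQKELNWDRGNSSG
LRITAVPSGDKLAARHHLATAILKSEYHDTLRGGGMHRQNIAAAAVAWQFRGLTQIAGQRSACRASNTRD
KPQKIECVNRCPTALAGLVAKEFPLFKTVDAPLQVYPVLGHIPRIGGVVVIKPVIALVAYAMFFEVRCPQ
GLLGRLDDYDKLQGKISRLTNEKSIPFGFGYLRPIRLGNHGSVFFLRLATICAFPREGRERDEALGEHVA
VLSEVGDHSRIDDVVFTQWHEIIANRAEVKQELLLFDLEDAIRDIVTQIMGFQSISDAMALLSIRKYSGI
DEHGKAAVYGSPDQANFEVGAYYKLKDWIVITKFTVVLLIMQKPEKKAIHISRGSYTGVLADSQRPVLLA
VSSPLGSEDIGYWAGVYVNAKNIPEKVVRVMQIMPGKPVNSDFGGVKSDTDVCAIALLNDSIGERMFIAL
LLELTHQQCHTLQVVYTYKENGEGSAPYQYMETASVSHPGEIKDAKVLADKEFIQHGITGSPLEIEWQVS
VPANMQRILEANDNNEDKSSKVGNEYCGKIRWRDLDKIYSLGGNRRDVIYSKTLAFKTIFPMGSVALAKF
LSFRIEDEFQTSLQEPESVGVNDLKLVELELAVINGDGGLDLELFVRMKIHITAMVFITRLDGEVVGVAL
CVNIDAKGMMVKLHIRICDNELLSAAYLNESTEWENNRPDEKVEAVDLIKRRIGAGSNYPGCLRVHRNEE
KETANGGMIKISTGGREFLKDPVAFPRPQRVHNISKSENPESIALPIHKIAYETRLSNICLIIKSEPPDI
LADVTVLDNEVCAIEDKEDGRIGATDNEIDSKGAIIQTLIESDRAVEFAYCLQKHLGKNKKSDGSEFRLV
VPSKTRAQPSMSFMSSLCNFEAAYMCNGKSKQSKDLALKEKQSVEADTTRDPNGARGTQINLRYTMSELL
ELELAGDLMKSVAAGPTLIVLSGFTIRLDETGGQLYTQEDDITKLTGYPFPEFLAKPDVKEPELLVYADA
GELGVVILMFTFYKDTTPVRVGIHDDALTNRRRDKDSRVAQKVGHIMVKDYERVQRDRAMAIAIPVCGAS
KGKRLYKSKYIETDTKAASENQLGIHFKVMERLAIVCNLITNDEQCNVSLQQCKTGDIRHYQSLGLREKQ
CHPELSRLDTFRDITVELLEDPLTLAEHHRVLKARSEGELLPGVSSTCLKKEAKKEERSLKTESSHDGAA
MRYLIEAIAVHKQEIIYSTVDGAPLDKAAFSRCFLTAYAALIVQNNDIESVLPGLLNVLATNLAGRNSSL
IHDHDIKVESEQEQLSHVGEPRALKFAEHQKAVSAGIVACSADQRLDRRLEDTKILSEVNVVLVEQCSIS
RYAVIYAAFLSDPRIQVNTANRGLIIKLNTSTLMLTGLGNQWVHRLRPAQCAERLDAKLHDVASSRFRQS
DIMKVGENTQDSIEGDIDSCLGVLIATGQPNGSGTLTTIVLKAAMGGPMTQGDSRLQAVNPIQPLYLVRA
LRLIGFVCSPSVTAPFGRNKILNSAYNTPKLQHIYVINLNVMTECATSTNTQADDAAGVYTTYNNDVPQP
EKFRGHMELNIVKIPTLQLAKTERIDDFNNLVDEDDIAQCAAEKLAQDEIMMCATGKLTDMSKLMYSHDM
HIMPIRFDDEHCTAHEHLAMRDPLEDSMIADAVVPNVGVEIIQVNIAPENIRMSTHYSKLLNYTVVFDGW
LKCGLNVQINEQHHAIRGGKKALAGHFGRIRRFVRDLTSSPVLFRMDAEEVGGAELPATCDNNVMAPHET
ENLIFDKRHHVSGYRMDFFNIPSILFVLPELTAANGHALGSLESGLPLRRCVENVDLVLEFLATVEKRMT
PQVTDLAMFYFRPVTTRPLMA
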