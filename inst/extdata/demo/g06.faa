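>p1
MRIEEVPFECVDTVGGCYDCTLIFATHEPLKNYKMDSFQFCVTVFQIIEEHLVPWSTNKMSIGAPQFKSN
LLAWTQQDGRMFSTTVCGGGYRCLNKICCNQCCHFLTTFDQQAKDPMYTYEYMTKTPTYATACISDFPNA
WFRGSLH
>p2
KKDVRRYSAGMKYPIMRCGANSTMVCLEYRHTDYVKMGLKWKMMELTNGRKLVHQNWLFCDCESEGYYVV
QAEDGNHNFVHPCDARYMKLTWVNLKWRQDYLCTVWQTL
>p3
FPVWWLSCEHAQYWNWGNWHWCGKMGFQLRAKLTNAMEDGFRYCEYKQQAVLAIYFGQEKISNLQMCSQR
TWWLPGAMPLPCTRIEGLYSNSWDHDLLHWPLQMPDLWCHYMYAGLKNPVRRMIPQF
>p4
GPDPLWSPPISGGIFKLMAQEHMLICPYSIDKSMPHVHFYVHTDSIWVLRTDDSLCIAPHMMPFCRFQFT
VCVHPCNKYIYQAQVCFLNDVVVRAIWIYCCYWMRVIACETNYWHKWMMNTCYHTEDWATECI
>p5
DPCFKMLQAAQYMKWECKDNCSVTYIIWRGDARNKLMGVVTGNTMIVMWAMTTNMVAGCQFAVERHQLDH
DGFVKDDKPNLTCYTNFWLSALHCEYIRQTFTTSYGDQKNKQDEDHAFEINNNRKDDK
>p6
HCPTRRYDPECFVVAEVFDLDQLLKHGPIFWYMTHLREYDAFFWTMAAVDFHGSPAWVFQLCSKHCRRDC
TDMFADQGSLIKDCGCSKFTNYEGCDVTVMISYAWSIYVLLWPNIGHH
>p7
FAWMCVLGENGTQAMYWFDPWVYQCAQHRGNYMLTLWLKIWHEISMLYVHIFVRCALKYTPGCWAMSWWF
IWSNRHARIGMHAYFQMTTTWQVLDTLAMPQPHIEQKYWQWRSDCGTLPLLDETVTLLLPIHFTKIWPAN
AGWPWFPQQY
>p8
NYIMQCQLCLDCFRWNVVMKIKIDILLCMLRYCLQWESRMWLCFWMVYMLFPLTDTLCFNRGAPKQNVHI
NNAWVTIARVQAGWMAAARVMALYKFGMFWGIWTNLIIHQRRMLWVTR
>p9
WPYDLSPVAKMFQDFMQSFLGEFNVHPLSECNPSRYNRSTTATLDTEMHLSHDGMFSPEWRIDKPFNELD
HGTYLYNYCVDRNRDYGLGMANDPFLSQAAMQAYDDTWTQAGGFTYYIKEHERHRSPTRAWISQMLRVCI
SFQHFNGTSFGFDYVWALMN
>p10
DRQATDAPCPMGGHNAWPDIRFMPREWDAPKTSTHNMNMFPFWLRCPNEHPWPSLASKDANHPKGQNVNM
KDKAQWNQNYSEPFEMAPKKPPIKCKRNVNRSNNIVMVPRHETEHFVPN
>p11
YQGCHQLIVDNWPSFFWINCAWCRAPCDAGKWDAFNGGQYDWCTRDDTEAIVTNCVYHGCDMGKDYCLNY
QLYETRNYNCGDNPTSQEIGRAHPFKTWGGWLRTNCCCEIFSWCFWLFPDSNEEETAVLILLCWDYYVWV
SPQRLF
>p12
CQHSEVKPAVNTRNHCNHQTPGTCFEIHIRYYMLNWDNKHCLGYLFYTYGCDNSMYKVHPLRNKSCHQPR
DWPTGGIWNKQGQCWKIPFQGAWIPMHNKRKMRMIQKMAIMNMCDRDEKYCGFTYKMDKKMCIYDTRSAM
PNRPTSDHCTQGIVHNYLWYTRVRQR
>p13
LLYGGKGHEARLCEICNNFNRLWMHDIHAWWDAYVDCSHADEYFAGQQACSETQPWFHMKMNECYSTVCD
KQQRYANPFAIIMDQCKHADAQ
>p14
AGNPFENEPMCVLFIHTQDDDDVFWVLSHQYCDRQLDWGIAEAPCHRYFFYANQPEHYPRVRICFRWQVP
VCQLIAWRMGQYLYVKFVDAAKYHMFNVYTVADINLNYRVHHCN
>p15
WWNQRNNICITARGFFPFQRFKWVNHMWNAKTWVENWKSLVSLGDQKLTNEIKHFHPVMSDAQRKEHDRH
YENKESEHINFQCLPPYPKPRGCQTYVRMMRGNLDQTMSYPYFGIKL
>p16
IACPKILPAPWPISTELKPWIIVQSGSPWEELFKEMPCTGGMALNPTIWTTYCHPMSDHSDRYAVNFIYL
VTTAQKWTCNGSYNYWKCGVGPSWMIYWDNVICYRHNPRLEFRLRMPKQITHVYHDNGQERPH
>p17
YHCVMYMLNHRENFAFYYMACFQDMMFERSYEDAEMWEVDPEVTNRWVDKYYPAAHEWNNVKEPQSQTHH
HVNCFMPENTDSKINMGVAPIACQTAAYGNMQFCVPMMNALICW
>p18
ITIREWYTHRNFDSYYQRMMFMVWQHPEGSFKGNTLDGCDSRRNTCHISLDNTFYDKVNFQMDQSWA
>p19
HYCGFVHQEPAYIWYHLKWFRKDCTGWPWSMPKFDQMHTDVLQQQKFTARSVSRSSIKEQLEMDTGMMLF
E
>p20
CFYCTTETQGATCGSSLDRHGNYLMDLKACPPWWFDSHFHHHYLVEMQVRLCAMECCQYKRIAWKLHWVD
RESPQYTVANCEWKEELQKLMFKVDEMFDYFIRQVPDSDYKMLIYQIDCKKSAQDHIFEKTTFWSMTPIP
LQFSQN
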