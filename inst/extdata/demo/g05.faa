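>p1
MRIEEVPFECVDTVGGCYDCTLIFATHEPLKNYKMDSFVFHVTVFRIDEEHLVPWSTNKMSIGAPQFMSN
LLAWTQQLGRMFSTTVCGGGYRCLNKICCNQCCWFLTTFDQQAKDPMYTYEEMRKTPTYATACISDFPNA
EFRGSLH
>p2
KKDVRRYSAGMKYPFMRPGANSTMVCLEYRHTDYVKMGLKWKMMELTNGRSLPHQNWLFCDCQSELYYVV
QAEHGTHNFVHPCDARYMKLTWVNLKWRQWYLCTVWQTL
>p3
FPVWWLSCEHAQYWNIGNWHWCGKMGFQLRAKLTNAMEDGFRYCEYKQQAVLAIYFGQEKISNLQMCSQR
TWWLPGAMPLPCTRIEGLYSNSWDHDLLHWPLQMPDLWCHYMYAGLKNPVRRMIPQF
>p4
GPDPLWSPPISGGIFKLMAQEHMLIDPYSHDKSMPHVHFSVHTDSIWVLRFDDSRCIAPHMMPFCRFQFT
VTVHPCNKYIYQADVCFLNDVVVRAIWIYCCYWMRVIACETNSWHKWMMNTCYHTEDWATECI
>p5
DPCFKMLQAAQYIKWECKDNCSVTYIIWRGEARNKLMGYVKGNTMIVMWAMTTIMVAGCQFAVERHQLDH
FLFWKDDKPHLTCYTNFWLSALHCLYIRQTFTTSYGTQKNKQDEDHAFEINNNRKDMK
>p6
HCPTRRYDPWCFKVAEVFDLDQLLKHGYIFWYMGHLNEYDAFFWTMAAVDFHGSPAWVFQLCSKHCRRDC
TDMFADQGWLIKDCGCSKFTNYEGCDVTVMISYAWMIAVLLWPNKGHH
>p7
FAWMCVLGENGTQAMYWFMPWVYQCAQHRGNYMLTLWLKIWHEISMLYVHIFVRCALCYTPGCWAMSWWF
IWSNRHARIGMHAYFFMTTTWQVLDTLTGPQPHIEQKYWQWRVDCGTLPLLDEVVTLRLPIHFTKIWPAV
AGWPWFPSQY
>p8
NYIMQCQLILDEFRWNVVMKIKIDILLCYLSYCLQWESWMWLCFWMVYMLFPLTDQLCFNWGAPKQNVHI
NNALVTIARVQAGWMAAARVMRLYKFGCFWGISTNLIIHQRRMLWVTR
>p9
WPYDYSPVAKMFQDWEQSFLGEFNVCPLSECNPSRYNRSTTATLDTEMHLSHDGMFSPEWRICKPFNEWD
HGTYLYNYCVDRNRDYGLFMANDPFMSQAAMQLYDDTWTQIGGQTYYIKQHERHRSPTRAWISQMLRVCI
SFVHFFGTSFGFDYVWAGMN
>p10
DRRALDAPCPMLGHNAWPDIRFKPREWDAPKTSTHNMNMFPFWLRCPNEHPWPSLASNDINHMKGQNVNM
KDKAQWNQNYSEPFEYAPKKPPQKCKRNVNRSNNIVMVPRHETEHFVPN
>p11
YQGCHQNTVDSWPSFFWINCAWCRAPCDAGKWDAFNGGQYDWCTRDDTEAIVTNCVYHGCDMGKDYCLNY
QLGETRNYNCGDNWTSQEIGRAHPFKTWGGWLRTNCCCEIFSWCFWLFPESNEEETAVLILLCWDYYVWV
SPQRLF
>p12
CSHSEVKPAVNTRNHCNHQTPGTCTEIHIRYYMVIWDNKHCLGYLFFTYGCDNSMYKVHPLRNKSCHQPR
DWPTGGIWNKQGQCWKIPMQGAWIPMHNKRKMRMNQKMAIMNMCRRDEKYWGFTYKMMKKMCIYDTRSAM
PYRPTSDHCTQPIVHNYLWYTRVRQR
>p13
LLYGGKHHEARLCEICNGSNRLWMHDIHAWWDAYEDCSHADEYFAGQQACSETQPWFHMKMNECYSMVED
KQQCYANPQAIIMDQCKHADAQ
>p14
AGDPFENEPMCVLFIHTQDCDDVFWVLSHYYCDRQLDWGIAEHPCHRYFFYAEQPEHYPRVRICSRWQVQ
VCQLIAWRMGQYLYVKFVDAAKYHMFNVYTVADINLNYRVHHCN
>p15
WWNQRNNICITAPGRFPFQRFKWVNHMWNAKTWVEYWKSLVSLGDQKLTNEIKHFHPVMSDAQRKEHDRH
YENKESEHINFQCLPPYPKPRGCQTYVRMMRGNLDQTMSYPYFGIKL
>p16
IACPKILPAPWPISTELKPWIIVQSGFPWEELLKEMPCTGGMALDPTIWTTYCHPMPDHSMRYAVNFIYH
VTTAQKWTCNGSYNYWKCGVGPSWMIYWDNVICYRHNPRLEFRLYLPKNITHVYHDCCQERPH
>p17
YHCVMYMLNHRENFNFYYQACFQDMMFFSSYEDAEMWEVSPEVTNRWVDKYYPAAHEWVNVKEPCPQTHH
HVNCFMRENTDSKINNGVAYIACQTAAYGRMQFCVPMMNALICM
>p18
ITIREWYTHRNFDSYYQRMMFMVCQHPEGSFTGNTLDGCDSRRNTCHISLDNTFYDKVNFMMDQSVA
>p19
HYCGFVHQEPAYIWYHLKWFRKDCTGWPWSMPKFDQMHLDVLQQQKFTIRSVSRSSIKEQLEMDTGMWLF
L
>p20
CFYCTTECQGATCSTSCDRHGNYLMDLKACPPWWFDSHFHHHYLVEMQVRLCAMECCQYKRIAWKLHWVD
RDSPQYTVARCEWKEELQKLMFPVIEMFDYFIRQVPDSDYKMLIYQIDCKKSAQDHIFEKTTFMSMTPIP
LQFSQN
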